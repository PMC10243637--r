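Package: pirnasig
Title: piRNA Biogenesis Signature Analysis for Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify PIWI-interacting RNA (piRNA) biogenesis
    signatures in small RNA sequencing libraries: adapter/UMI trimming and
    collapsing of raw reads, infrastructural-RNA filtering, a brute-force
    mapper for toy references with fractional multimapper weights,
    per-transposon 5'/3' end-coverage profiles with strand bias and
    first-nucleotide composition, ping-pong (+10 nt 5' overlap) and phasing
    (+1 nt 3'-to-5') linkage spectra with window z-scores, an "in-trans
    ping-pong" 9mer sum-product statistic with a spike-in calibration
    simulation, genomic tile quantification separating somatic from germline
    piRNA sources, and a synthetic-data generator that emulates the
    statistical structure of ovarian and embryonic piRNA pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils,
    methods,
    tools,
    BiocGenerics,
    stringi,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
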