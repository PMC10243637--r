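# pirnasig

Quantitative analysis of piRNA biogenesis signatures in small RNA
sequencing libraries.

PIWI-interacting RNAs (piRNAs, here defined as mapped reads ≥ 23 nt)
silence transposons in animal gonads and are produced by two
mechanisms that leave distinct footprints in sequencing data:
**ping-pong** (reciprocal slicing, yielding sense/antisense pairs whose
5′ ends overlap by exactly 10 nt) and **phasing** (head-to-tail
fragmentation by Zucchini, yielding consecutive same-strand piRNAs with
a 3′→5′ spacing of +1 and a downstream-uridine preference). `pirnasig`
measures:

* per-transposon 5′/3′ **end-coverage profiles** (CPM per million
  genome mappers), antisense **strand bias**, and per-length
  first-nucleotide (1U) composition;
* **linkage spectra** with window-of-20 z-scores — ping-pong at the
  +10 5′ overlap and phasing at the +1 3′→5′ offset:
  `z = (f_link − mean(f_bg)) / sd(f_bg)` with the background taken over
  the other 19 window offsets;
* the **in-trans ping-pong statistic**: for every piRNA the 9mers
  `g1g9` (first nine bases), `last9`, and `g2g10_revComp`
  (reverse-complemented bases 2–10) are tallied into frequency profiles
  scaled to sum 1000, and the statistic is
  `Σ_s f_g1g9(s)·f_g2g10rc(s) − Σ_s f_last9(s)·f_g2g10rc(s)`,
  the background-subtracted sum-product over shared 9mers. By spike-in
  calibration (pairs at 100 CPM), one linkage unit ≈ 1% of reads in
  slicing-triggered pairs;
* **genomic tile quantification** (0.5 kb unique-mapper tiles at ≥ 85%
  25mer-unique coverage; 0.2 kb all-mapper tiles with 1/n_hits
  multimapper weights) and somatic-tile calls from matched whole-ovary
  versus embryonic libraries (> 10-fold ovary excess), with annotation
  priority piRNA cluster → gypsy antisense/sense → mRNA exon;
* a **synthetic-data generator** producing toy genomes, matched
  ovary/embryo libraries and read pools with engineered ping-pong
  pairs, phased trails, strand bias and power-law abundances under
  known parameters.

## Worked example

```r
library(pirnasig)
set.seed(1)

# a 1e6-count random piRNA pool with 5% engineered in-trans pairs
pool <- inject_pairs(sim_pirna_pool(1e5, total = 1e6), percent = 5)
intrans_estimate(pool)
#> in-trans ping-pong: foreground 8.315, background 3.830, estimate 4.49%

# ping-pong and phasing signatures on a simulated transposon
aln  <- sim_pingpong_te(8000, n_pairs = 1000, n_background = 1000)
prof <- end_profile(aln, "TE", 8000, genome_mappers = 1e6)
round(c(pingpong_z = pingpong_spectrum(prof)$z,
        phasing_z  = phasing_spectrum(prof)$z), 2)
#> pingpong_z  phasing_z
#>      70.22       0.01
```

The in-trans estimate reads directly in percent: the injected 5% of
pair reads are recovered as 4.49% (within the ±1-point sampling error
of a single pool) over the residual background of a random pool. The
ping-pong z-score of ~70 reflects the engineered +10 overlap; the
phasing z-score on the same pool stays at background level.

A thin command-line front end over the same functions is installed at
`inst/cli/pirnasig.R` (subcommands `simulate`, `calibrate`, `intrans`,
`linkage`, `report`; every output directory receives a JSON run
manifest).

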