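---
title: "Quantifying piRNA biogenesis signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying piRNA biogenesis signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pirnasig)
```

## Background

PIWI-interacting RNAs (piRNAs) are 23–32 nt small RNAs that silence
transposons in animal gonads. Two biogenesis modes leave distinct
sequence and positional footprints in small RNA sequencing data:

* **Ping-pong**: reciprocal slicing between sense- and antisense-loaded
  PIWI complexes produces piRNA pairs whose 5′ ends overlap by exactly
  10 nt on opposite strands.
* **Phasing**: the endonuclease Zucchini fragments a precursor head to
  tail, so consecutive piRNAs on the same strand show a 3′-to-5′ spacing
  of +1, and the base immediately downstream of a 3′ end is preferentially
  a uridine (as is the first base of a piRNA, the 1U bias).

`pirnasig` quantifies these footprints, plus two whole-library analyses:
an *in-trans ping-pong* statistic that detects slicing-triggered phasing
between piRNAs from different loci genome-wide, and a genomic-tile
quantification that separates somatic from germline piRNA sources by
comparing whole-ovary and embryonic (germline-only) libraries. A
synthetic-data module generates pools with all of these features under
known parameters, so every stage is testable without sequencing data.

## Preprocessing model

Reads are adapter-trimmed by an exact match of the first 10 adapter
bases (leftmost hit wins — the trimming tool used historically for such
libraries leaves this choice open), stripped of 4 nt terminal UMIs,
size-selected to 18–40 nt, and depleted of size-selection spikes and
infrastructural RNAs (rRNA/snoRNA/snRNA/miRNA/tRNA, one mismatch,
either orientation). miRNA-matching counts are kept as a normalisation
denominator. Reads of 23 nt or longer count as piRNAs downstream;
18–22 nt reads are retained in files but never contribute to profiles.
Reads containing N are excluded from mapping and k-mer statistics.

The built-in mapper is an exhaustive Hamming-distance search
(`Biostrings::matchPattern`) over both strands, with `all` and
`best_strata` reporting modes and fractional weights `1/n_hits` so that
each mapped read distributes unit mass over its mapping instances. It is
intended for toy references up to a few megabases; for real genomes the
pipeline ingests externally produced BED/SAM alignments instead —
re-implementing an FM-index is out of scope.

## Linkage spectra and the z-score window

For a transposon profile, the ping-pong frequency at overlap $k$ is

$$f(k) \;=\; \sum_p \mathrm{five}_S(p)\,\cdot\,\mathrm{five}_{AS}(p+k-1),$$

the abundance-weighted co-occurrence of sense and antisense 5′ ends, so
$k = 10$ is the ping-pong position. The phasing frequency is the same
product between 3′ and 5′ ends on one strand, evaluated in the strand's
own 5′→3′ orientation so that head-to-tail trails always score at +1
(on the antisense strand a naive reference-coordinate reading would put
the signal at −1). Frequencies are evaluated over a window of 20
consecutive offsets (1–20 for ping-pong, −9–+10 for phasing, symmetric
around the linkage position as in the standard spectrum plots).

The z-score is the deviation of the linkage-position frequency from the
mean frequency divided by the (population) standard deviation. One
numerical subtlety is deliberate: the background mean and standard
deviation exclude the linkage position itself. If the linkage value is
included, the z-score is algebraically capped at $\sqrt{19} \approx
4.36$ for a 20-value window, and a strong signal becomes
indistinguishable from a moderate one; excluding it leaves the null
distribution approximately standard normal while letting genuine
signals reach arbitrarily large z. `linkage_zscore()` exposes both
readings. A zero-variance background (e.g. a perfectly clean
constructed pool) is reported as $z = 0$ with a flag rather than
infinity.

## The in-trans ping-pong statistic

Target slicing requires complementarity between guide positions g2–g10
and the target, and the slice site defines the responder's 5′ end, so a
responder's first nine bases (g1g9) equal the reverse complement of the
guide's g2–g10. For every piRNA read three 9mers are recorded — g1g9,
the last nine bases (last9), and the reverse-complemented g2–g10
(g2g10_revComp) — and per-category frequency profiles are scaled to sum
to 1000 (the intermediate per-million-genome-mappers normalisation
cancels under this rescale and is kept only as an attribute). The
statistic is

$$L \;=\; \sum_{s \in \text{9mers}} f_{\mathrm{g1g9}}(s)\; f_{\mathrm{g2g10rc}}(s)
\;-\; \sum_s f_{\mathrm{last9}}(s)\; f_{\mathrm{g2g10rc}}(s),$$

where the last9 term measures the genomic-composition background, since
read 3′ ends carry no slicing information. Frequencies are kept as exact
shares of the pool until the final scaling so the sum-to-1000 invariant
holds without drift.

### Calibration

One injected pair species — two reads with an exact 10-nt complementary
5′ overlap, each at 100 counts per million of the final pool —
contributes exactly $2 \times (100/1000)^2 = 0.02$ linkage units (the
factor 2 because the pairing holds in both directions). Reaching a pair
share of $p\%$ therefore takes $50p$ species regardless of pool size,
and the expected linkage is $p$: one linkage unit per percentage point.
`calibrate_intrans()` verifies this empirically by injecting 0/1/3/5/10%
pairs into random pools (5 replicates each) and fitting the
least-squares slope, which should be 1 within sampling error. Injected
9mers are drawn to collide with nothing already in the pool, isolating
the designed signal; the estimator applied to biological-style pools
then reads background-subtracted linkage directly as "percent of reads
in pairs". Estimates on null pools may be slightly negative and are
reported as-is. In cross-library mode the g2g10_revComp profile comes
from one pool (e.g. an immunoprecipitated PIWI-bound library) and the
g1g9/last9 profiles from another (the total pool).

## Genomic tiles and the somatic compartment

Whole ovaries contain somatic and germline cells; 0–2 h embryos contain
germline-derived material only. Tiles whose ovarian piRNA output
exceeds the embryonic output more than 10-fold are attributed to the
somatic compartment. Two resolutions are used, following the analysis
design: 0.5 kb tiles with genome-unique mappers for scatter plots
(restricted to tiles at least 85% covered by unique regions, assessed
with artificial 25mers where an occurrence on either strand counts
against uniqueness), and 0.2 kb tiles with all mappers weighted
`1/n_hits` for somatic quantification. Reads are assigned to the single
tile containing their 5′ end, since a piRNA's identity is defined by
its 5′ end. Tiles are annotated by coverage (at least half the tile,
boundary inclusive) with conflicts resolved in the order piRNA cluster
→ gypsy antisense/sense → mRNA exon. The somatic composition report
gives each class's share of somatic piRNAs and the somatic share of all
ovarian piRNAs.

## Synthetic data: what it does and does not emulate

The generator produces toy genomes with embedded transposon fragments
(a uni-strand, flamenco-like cluster with all-antisense insertions and
a dual-strand germline cluster), matched ovary/embryo libraries, and
read pools with engineered ping-pong pairs, phased trails, strand bias,
1U/downstream-U biases and power-law abundances. Default parameters are
the study conditions of the analyses: read lengths 23–29 nt, 1U
probability 0.75, downstream-U probability 0.7, 10× somatic fold, pair
spikes at 100 CPM. Species abundances follow a Pareto tail with index
1.5, which puts roughly 10–20% of the pool mass into species at or
above 100 CPM, matching the regime in which the calibration spike level
was chosen. Null pools for the in-trans statistic use equal
multiplicities ("pools of distinct reads"); heavy-tailed abundances are
used where the calibration design asks for them. U-bias parameters are
made exact by forcing a non-U base when the biased draw fails —
otherwise the realised frequency would be $p + (1-p)/4$ rather than the
configured $p$, and parameter-recovery tests would be biased.

The generator does **not** emulate sequence evolution of transposon
families, transcription-level structure (promoters, splicing),
sequencing error, or ligation biases. Passing recovery tests therefore
demonstrates correctness of the statistics under the assumed data
structure, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Population (n-denominator) standard deviation in z-scores, fixed for
  reproducibility; zero-variance windows give z = 0 with a flag.
* Pseudocount 0.1 (CPM or normalised units) in ovary/embryo ratio
  calls with zero denominators.
* Redundancy removal among transposon consensus entries uses a greedy
  rule on the top-150 ranked entries: a lower-ranked entry is absorbed
  when more than half of its weighted reads also map to a retained
  entry (the share threshold is configurable and an audit trail is
  returned). Ranking uses weighted counts.
* Terminal-inverted-repeat transposons (e.g. mariner) confound strand
  bias; they are handled as a user-supplied exclusion list rather than
  by automatic TIR detection.
* The last partial tile of a contig is kept only if at least half the
  tile width; pair-injection rounds the species count and reports the
  achieved percentage.
* Problem sizes in the test-suite simulations (pools of 10^5–10^6
  counts, references of 5–8 kb, 20-seed null panels) were chosen as the
  smallest sizes at which the statistics operate in their intended
  regime — dense linkage windows and sub-percent binomial errors.

## A worked example

```{r, eval = FALSE}
set.seed(1)
# a pool with 5% engineered in-trans pairs
pool <- inject_pairs(sim_pirna_pool(1e5, total = 1e6), percent = 5)
intrans_estimate(pool)
#> in-trans ping-pong: foreground 8.315, background 3.830, estimate 4.49%

# ping-pong and phasing signatures on a transposon
aln <- sim_pingpong_te(8000, n_pairs = 1000, n_background = 1000)
prof <- end_profile(aln, "TE", 8000, genome_mappers = 1e6)
pingpong_spectrum(prof)$z    # large
phasing_spectrum(prof)$z     # background level
```

## Known limitations

The brute-force mapper scales to toy references only; real-genome
alignments must be imported. The in-trans statistic assumes exact
g2–g10 complementarity — partial-complementarity slicing models are out
of scope. Tile annotation relies on the supplied interval tables; no de
novo cluster discovery is attempted. Real-library results additionally
depend on adapter chemistry and depletion steps that the preprocessing
model only parameterises coarsely (quality filtering defaults to a mean
Phred threshold of 20 and is configurable upstream of this package's
input formats).
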