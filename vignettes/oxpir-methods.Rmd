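---
title: "Methods: oxidation-based piRNA cluster reference construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oxidation-based piRNA cluster reference construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oxpiR)
```

This vignette documents the models, parameter choices and numerical
decisions behind `oxpiR`, and states what the synthetic-data tests do
and do not demonstrate about real data.

## The reference-construction model

piRNAs carry a 2'-O-methyl group at their 3' end; periodate oxidation
destroys RNAs with unmodified 3' ends. An oxidized testis small-RNA
library is therefore treated as (nearly pure) piRNA, and a cluster
reference is defined operationally: map the oxidized reads exactly to
the genome, and merge placements separated by at most 1 kb into
clusters. No assumption about base composition, strand structure or
transcription units is made — deliberately, because piRNA sequence
conventions learned in model organisms need not transfer to
un-studied genomes, and because dedicated cluster callers that build in
1U/10A composition can return very little on such data. The cost of
the short 1 kb merge distance is a large, fragmented cluster set; the
benefit is resolution for differential expression between closely
spaced clusters. Merging is strand-agnostic by default, matching the
plain `bedtools merge -d 1000` semantics (book-ended or overlapping
intervals always merge; a `stranded` switch preserves the per-strand
alternative).

Two filters turn the preliminary set into the final reference:

* **count floor** — a cluster with read count < 10 in *both* the
  oxidized and the untreated testis library is unexpressed;
* **oxidation ratio** — a cluster whose oxidized/untreated count ratio
  is < 0.1 is dominated by oxidation-sensitive RNA (abundant
  miscellaneous RNA in testis), not by piRNA.

Edge rulings: an untreated count of 0 with a positive oxidized count
gives ratio +Inf and passes (the cluster is oxidation-resistant); an
oxidized count of 0 with positive untreated count gives ratio 0 and is
excluded — the stated intent of the ratio filter is precisely to remove
such oxidation-sensitive material. Because retention is a conjunction
of the two rules, their order of application is irrelevant; the tests
assert the conjunction on the full (ox, testis) ∈ {0..60}² grid.

## Read-level prefiltering

Reads outside 25–32 nt are removed (both bounds inclusive). A read
"hits" a known miRNA hairpin or tRNA when its sequence or reverse
complement occurs as an exact substring of a reference sequence; exact
matching is the strictest reproducible reading of a sequence-database
screen, and a Hamming-distance-1 option is exposed but off by default.
RepeatMasker-based exclusion operates on mapped positions (the `.out`
file is genome-anchored) with any-overlap (≥ 1 bp) semantics, removes
the classes tRNA, rRNA, Simple_repeat and Low_complexity, and retains
transposon classes — piRNA clusters are expected to be TE-rich, so
removing LTR/LINE/SINE/DNA overlaps would destroy the signal. Unknown
class strings are retained with a warning (conservative). The
low-abundance floor (unique-sequence count ≥ 10) applies to the
oxidized library before reference construction; it is optional
elsewhere.

## Exact mapping

The mapper is a seed-and-verify hash index: every genomic 25-mer (the
minimum read length, so one lookup per read and strand suffices) is
stored with its scaffold and offset; a read's first 25-mer proposes
candidate placements, each verified by full-length string comparison.
This reproduces "output all matches, no mismatches" semantics exactly:
all placements on both strands are reported, a palindromic placement is
reported once per strand, reads containing N never match (exact
matching cannot place an ambiguous base without a mismatch policy), and
no cap is imposed on placements per read (`max_hits` is available).
Multi-mapping reads contribute their full collapsed count at every
placement; a fractional (1/n per placement) counting mode exists for
sensitivity analyses. The test suite proves hit-set equality with a
naive substring-scan oracle on random genomes and cross-checks single
loci against `Biostrings::matchPattern`.

Coordinates are held in `GRanges` (1-based, closed) inside the package
— the natural container in this ecosystem — and converted to BED's
0-based half-open convention at every file boundary; cluster
identifiers use the BED-style `scaffold:start-end` form so the id
matches the BED line it labels.

## Classification thresholds

A cluster is *testis-only* when `sum(somatic) < s_max` and
`testis > 50` (strict), and otherwise *soma-and-testis* when testis and
at least one somatic library reach count ≥ 10. The threshold `s_max`
defaults to the total number of sequenced libraries in the experiment,
following the stated rule that ties it to the sample count of the
design (10 libraries → 10, 6 → 6); it is overridable, and ovary is not
counted as somatic (germline tissue), also configurable. The two label
rules can in principle both hold (e.g. one somatic library ≥ 10 while
the sum stays below `s_max` with a large testis count); evaluating
testis-only first keeps the sets disjoint, matching their intended
reading as a partition. The suite asserts the labels against the raw
inequalities over an exhaustive count grid.

## Base statistics

Positional composition defaults to read-count weighting (distributions
over sequenced piRNAs); unique-sequence weighting is exposed because
abundance weighting can be dominated by a few species. Composition is
reported in RNA letters (U). The pathway ratio counts primary reads
(1U and not 10X) against secondary reads (not 1U and 10X), X ∈ {A, G};
all other reads are excluded, and a zero denominator is flagged
undefined rather than silently dropped. Under uniform base usage the
ratio has closed form (¼·¾)/(¾·¼) = 1, which the tests verify by
simulation. The chi-square bias test compares observed base counts at
one position against uniform ¼ (df = 3); uniformity is the natural
null absent an external background, and genome composition can be
passed as `expected` instead.

## TE annotation

The enrichment unit is the distinct TE: a TE hit by many clusters
counts once, so the compared quantity is "fraction of (hit | library)
TEs in class c", tested per class with a two-proportion chi-square with
continuity correction and flagged at p < 0.1 / 0.05 / 0.01. Raw
p-values are reported; any multiple-testing correction is left to the
caller. The internal matcher (exact 15-mer seed, greedy ungapped
extension stopping when the accumulated mismatch fraction exceeds
1 − identity, minimum alignment length 30) is a test-scale matcher for
synthetic data, not a BLAST replacement; production runs should feed
12-column BLAST tabular output through `engine = "external"`. Its hits
are verified in the tests against an exhaustive all-diagonal,
all-window local-identity oracle.

## The differential-expression substitute

A full shrinkage-GLM stack is out of scope; the built-in test is a
self-contained exact negative-binomial test in the spirit of the
pre-GLM generation of count-based testing:

* size factors by median-of-ratios, rescaled to geometric mean 1;
* per-cluster method-of-moments dispersion from pooled within-group
  variances of normalized counts, shrunk (prior weight 10 df) toward an
  `a0 + a1/mean` trend fitted across clusters, with a Poisson fallback
  when the estimated variance does not exceed the mean;
* a two-sided conditional test on the per-group count sums: the
  probability of group-A totals at most as likely as the observed one,
  conditioning on the overall total;
* `log2fc = log2((mean_B + 0.5)/(mean_A + 0.5))` on normalized means —
  the 0.5 pseudocount keeps fold changes finite on zeros, which the
  data contain in abundance.

The screens are exactly the printed conventions: an expression filter
(at least one group mean raw count > 10 and |log2FC| > 2) and a DE
filter (fold change > 4, i.e. |log2FC| > 2, with p < 0.05; "fold
change > 4" is read as a threshold on the normalized-mean ratio in
either direction). Calibration is asserted by simulation: type-I error
≤ 0.075 at α = 0.05 over 2000 null NB clusters (mean 200, dispersion
0.2, 3 vs 3) and power ≥ 0.8 for planted 8-fold changes under the DE
filter. Externally computed per-cluster p-values can be substituted via
`p_external` to reproduce an exact third-party stack. Direction and
fold-change estimates are cross-checked against DESeq2 in the suite;
DESeq2 is never used as the implementation.

## The synthetic-data generator

`simulate_genome()` / `simulate_sample()` emulate the statistical
structure the pipeline assumes, with defaults chosen once as the study
conditions:

* read lengths 25–32 nt peaked at 28 (mode probability 0.30);
* germline libraries with P(1U) = 0.77 and P(10A) = 0.491; somatic
  libraries with P(1G) = 0.5 and P(10U) = 0.4 — germline simulations
  therefore show a higher 1U/10A pathway ratio than somatic ones, as
  the statistics module must detect;
* 20 cluster loci (0.8–2.5 kb) spaced ≥ 5 kb (beyond the 1 kb merge
  distance, so ground truth is unambiguous) on 3 × 200 kb scaffolds;
  each cluster expresses 40 discrete piRNA species with log-normal
  abundances (sdlog 1) — discrete species are what makes a ≥ 10-read
  floor meaningful, and they reproduce the observed ~30% of unique
  sequences below 10 reads at a 10⁵ library depth;
* contaminants at realistic clean-read rates (0.1% miRNA-hairpin
  windows, 0.08% tRNA windows, 0.15% random-genome degradation);
  oxidation retains piRNA species fully and only 1% of contaminants, so
  the oxidation-ratio filter has genuine work to do;
* 6 of 20 clusters are germline-only; tumor libraries scale 5 + 5
  shared clusters by ×4.5 and ÷4.5; replicate noise is log-normal with
  sdlog 0.1, small because libraries model pools of many individuals;
* 40% of clusters carry a planted TE copy at 3% divergence, each from a
  *distinct* library family — with shared families, reads from one
  cluster's copy map exactly into another's and the ground-truth labels
  stop being consistent with the reads the generator emits.

The per-read base biases live in the *choice of species start
positions* (positions are accepted so that the strand-aware bases at
read positions 1 and 10 follow the target distributions), never in
edits to the read — every simulated piRNA read is an exact genome
substring and survives exact mapping.

All randomness flows from one master seed; per-library seeds are
derived deterministically so single libraries are reproducible in
isolation.

What passing these tests shows: the pipeline's operations implement
their definitions exactly, and the composition recovers planted truth
at realistic depth and contamination. What it does not show: robustness
to sequencing error and adapters (not modeled; inputs are assumed
clean), to genome assembly artifacts (scaffolds are random sequence,
so 25-mers are essentially unique outside planted repeats, which
understates multi-mapping in real genomes), or to biological dispersion
larger than pooled-sample noise.

## Problem sizes and numerical choices

The default simulated experiment (3 × 200 kb genome, six 10⁵-read
libraries, 20 clusters) runs the whole pipeline in well under a minute;
the validation suites use 1000 random merge instances, a 50 kb mapping
oracle with 500 reads, exhaustive 61² and 8⁶-scale threshold grids,
10⁵ random 28-mers for the pathway-ratio closed form, and 2000 null
clusters for test calibration — sizes at which the brute-force oracles
remain exact and fast. Ties in nearest-gene annotation break to the
lower-coordinate gene; signed distances are positive when the gene lies
right of the cluster. Proportion denominators exclude N bases; empty
read sets and all-zero count matrices are hard errors rather than NaN
propagation.

## Known limitations

* The exact mapper holds the k-mer postings of the genome in memory —
  appropriate for the scaffold-scale genomes of the tests and for
  moderate genomes, but a disk-backed index would be needed for
  gigabase genomes.
* The internal TE matcher is ungapped; indel-containing TE copies are
  only found via the external BLAST route.
* The NB test shares one trend-shrunk dispersion model across all
  clusters; with few clusters the trend fit is weak, and with strong
  per-cluster dispersion heterogeneity the test is less calibrated than
  a full shrinkage GLM.
* The classification threshold rule ties `s_max` to the number of
  libraries, which is a convention, not an estimate; designs with many
  somatic libraries should consider overriding it.
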