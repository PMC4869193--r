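# oxpiR

De novo piRNA cluster reference construction from oxidized small
RNA-seq, with downstream cluster quantification, germline/soma
classification, sequence-bias statistics, transposable-element
enrichment and differential-expression filtering.

## The problem

PIWI-interacting RNAs (piRNAs) are 25–32 nt small RNAs that silence
transposons, mainly in the germline. They are poorly conserved, so for
most species no piRNA annotation exists and a reference must be built
from the data itself. The experimental handle is 3'-end
2'-O-methylation: periodate (NaIO₄) oxidation degrades RNAs with
unmodified 3' ends (miRNAs, tRNA fragments, degradation products) while
piRNAs survive, so an oxidized testis library is strongly enriched for
genuine piRNAs. `oxpiR` turns a paired oxidized / untreated testis
design into a genome-wide cluster reference, and then quantifies,
classifies and compares all remaining libraries against it.

The pipeline, stage by stage:

1. **Prefilter** every library: keep 25–32 nt reads, drop reads whose
   sequence (or reverse complement) occurs inside known miRNA hairpins
   or tRNAs, drop mapped positions inside structural-RNA/simple-repeat
   RepeatMasker classes (transposon classes are retained — clusters are
   expected to be TE-rich), and, for the oxidized library, drop unique
   sequences sequenced fewer than 10 times.
2. **Map** reads to the genome exactly, reporting *all* placements on
   both strands (k-mer seed + full-length verification; no mismatches).
3. **Merge** oxidized-testis placements separated by ≤ 1 kb into
   clusters (bedtools `merge -d 1000` semantics) — the preliminary
   reference.
4. **Filter** the reference: a cluster is kept unless its read count is
   < 10 in both the oxidized and the untreated testis library, or its
   oxidized/untreated count ratio is < 0.1 (oxidation-sensitive RNA,
   not piRNA).
5. **Quantify** all libraries on the final reference and **classify**
   clusters: *testis-only* (somatic count sum below the sample-number
   threshold and testis count > 50) versus *soma-and-testis* (testis
   and at least one somatic library with count ≥ 10).
6. **Base statistics**: positional A/C/G/U composition and the
   primary/secondary pathway ratio — primary-pathway piRNAs carry 1U
   (uridine at position 1) and not 10A, secondary ("ping-pong") piRNAs
   carry 10A and not 1U; ratio = 1U¬10A / ¬1U·10A, with a 10G variant
   and a chi-square bias test.
7. **TE annotation**: match cluster sequences against a classed TE
   library (≥ 90% identity; internal seeded matcher or external BLAST
   tabular input) and test per-class enrichment of hit TEs against the
   library make-up with a two-proportion chi-square test.
8. **Differential expression** between tumor and benign-control groups:
   median-of-ratios normalization and a two-sided exact
   negative-binomial test (method-of-moments dispersion shrunk toward a
   1/mean trend), with the screens fold change > 4 (|log2FC| > 2) and
   p < 0.05.

A synthetic-data generator (`sim_config()`, `simulate_experiment()`)
emits genomes with planted clusters, TE copies, contaminants and
role-specific read sets with known ground truth, so the whole pipeline
is testable end to end without any external data.

## Worked example

```r
library(oxpiR)

cfg <- sim_config(seed = 7, depth = 2e4)   # 20 planted clusters, 6 libraries
exp <- simulate_experiment(cfg)
res <- run_pipeline(exp$genome, exp$reads, exp$sample_sheet,
                    mirna = exp$truth$mirna, trna = exp$truth$trna,
                    mask = exp$truth$mask, te_library = exp$truth$te_library)

cat("clusters:", length(res$reference$preliminary), "preliminary,",
    length(res$reference$final), "final\n")
print(res$accounting)
print(res$base_stats, digits = 3)
s <- res$de_summary
cat(sprintf("DE (IM vs HP): %d down (%.1f%%), %d up (%.1f%%) of %d tested\n",
            s$n_down, s$pct_down, s$n_up, s$pct_up, s$n_tested))
cat(sprintf("TE hits: %.0f%% of clusters; reference miRNA-clean: %s\n",
            100 * res$te$fraction_with_hit, res$te$mirna_qc$clean))
```

which prints:

```
clusters: 20 preliminary, 20 final
            label n_clusters fraction
1     testis_only          6      0.3
2 soma_and_testis         14      0.7
3           other          0      0.0
  sample_id    u1   a10 ratio_10A ratio_10G
1       hp1 0.177 0.174     1.017     1.112
2       hp2 0.169 0.173     0.972     1.025
3       im1 0.175 0.187     0.928     0.769
4       im2 0.171 0.190     0.884     0.744
5    testis 0.806 0.494     3.957    21.682
DE (IM vs HP): 3 down (15.0%), 2 up (10.0%) of 20 tested
TE hits: 40% of clusters; reference miRNA-clean: TRUE
```

All 20 planted loci are recovered and every cluster is classified to its
planted label. The testis library shows the planted germline signature —
U at position 1 in ~0.8 of reads, A at position 10 in ~0.5, and a
1U/10A pathway ratio ≈ 4 — while the somatic libraries (hp = benign
control skin, im = invasive melanoma) sit near composition 0.17/0.17
with ratios below 1, i.e. a secondary-pathway preference. The five DE
calls are the planted 4.5-fold changes recovered by the
negative-binomial screen (two of the planted ten fall just under the
strict |log2FC| > 2 cut at this depth).

A command-line wrapper for shell use is in
`inst/scripts/oxpir-pipeline.R` (subcommands `simulate` and `run`).

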