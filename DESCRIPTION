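Package: oxpiR
Title: De Novo piRNA Cluster Reference Construction from Oxidized Small
    RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds de novo PIWI-interacting RNA (piRNA) cluster reference
    sets for species without existing piRNA annotation, using paired
    oxidized (NaIO4-treated) and untreated testis small RNA-seq libraries.
    Provides the read-level exclusion cascade (length window, known
    miRNA/tRNA removal, repeat-mask exclusion, low-abundance floor), exact
    all-occurrence genome mapping of 25-32 nt reads, distance-based
    merging of mapped positions into clusters, oxidation-ratio reference
    filtering, cluster quantification and germline/soma classification,
    positional base-composition and primary/secondary pathway-ratio
    statistics (1U/10A), transposable-element class enrichment, a
    lightweight negative-binomial differential-expression test, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    BiocGenerics,
    jsonlite,
    optparse,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
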