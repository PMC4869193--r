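## Quantification of all libraries against the final reference, and the
## expression-based split into testis-only vs soma-and-testis clusters.

#' Quantify samples against the final cluster reference
#'
#' Maps each sample's prefiltered reads to the genome and counts reads
#' per reference cluster; reads not placed inside any cluster are
#' excluded from the matrix and tallied per sample.
#'
#' @param reads Collapsed read data.frame covering one or more samples
#'   (distinguished by `sample_id`), already prefiltered (length and
#'   contaminant screens; no low-abundance floor).
#' @param reference Final cluster GRanges.
#' @param index `genome_index` for the same genome.
#' @param sample_sheet Sample sheet data.frame (`sample_id`, `role`,
#'   `group`).
#' @param count_mode Passed to [count_reads_per_cluster()].
#' @return `pirna_counts` object; `attr(x, "unassigned")` holds the
#'   per-sample read totals that did not map inside any cluster.
#' @export
quantify <- function(reads, reference, index, sample_sheet,
                     count_mode = "full") {
  missing <- setdiff(unique(reads$sample_id), sample_sheet$sample_id)
  if (length(missing))
    stop("samples absent from sample sheet: ",
         paste(missing, collapse = ", "))
  sample_ids <- intersect(sample_sheet$sample_id, unique(reads$sample_id))
  aln <- map_reads(reads, index)
  counts <- matrix(0, nrow = length(reference), ncol = length(sample_ids),
                   dimnames = list(names(reference), sample_ids))
  unassigned <- stats::setNames(numeric(length(sample_ids)), sample_ids)
  for (sid in sample_ids) {
    sub <- aln[S4Vectors::mcols(aln)$sample_id == sid]
    cc <- count_reads_per_cluster(sub, reference, count_mode)
    counts[, sid] <- cc
    unassigned[sid] <- attr(cc, "unassigned")
  }
  roles <- stats::setNames(sample_sheet$role, sample_sheet$sample_id)
  cm <- count_matrix(counts, roles)
  attr(cm, "unassigned") <- unassigned
  cm
}

#' Classify clusters into testis-only and soma-and-testis sets
#'
#' A cluster is `testis_only` when the somatic read-count sum stays below
#' `somatic_sum_max` and the testis count exceeds `testis_min` (strict).
#' Otherwise it is `soma_and_testis` when both testis and at least one
#' somatic sample are expressed (count >= `expressed_min`).  Remaining
#' clusters are `other`.  Rules are evaluated in that order, keeping the
#' two sets disjoint.
#'
#' By default `somatic_sum_max` equals the total number of sequenced
#' samples in the sheet (the stated rule ties the threshold to the sample
#' count of the experiment); override to reproduce a specific design.
#'
#' @param cm `pirna_counts` object.
#' @param somatic_sum_max Threshold on `sum(somatic counts)`;
#'   default = number of samples in the experiment.
#' @param testis_min Strict lower bound on the testis count (default 50).
#' @param expressed_min Expression threshold (default 10, inclusive).
#' @param somatic_roles Roles counted as somatic; ovary is germline and
#'   excluded by default.
#' @param n_total_samples Optional explicit experiment size used for the
#'   default `somatic_sum_max` (e.g. when the matrix omits the oxidized
#'   library); defaults to `ncol + 1` assuming one unquantified oxidized
#'   library.
#' @return Named character vector of labels (`testis_only`,
#'   `soma_and_testis`, `other`) per cluster.
#' @export
classify_clusters <- function(cm,
                              somatic_sum_max = NULL,
                              testis_min = 50,
                              expressed_min = 10,
                              somatic_roles = c("somatic_control", "tumor"),
                              n_total_samples = NULL) {
  stopifnot(inherits(cm, "pirna_counts"))
  roles <- cm$roles
  testis_col <- names(roles)[roles == "testis"]
  if (length(testis_col) != 1L)
    stop("count matrix must contain exactly one testis column")
  somatic_cols <- names(roles)[roles %in% somatic_roles]
  if (length(somatic_cols) == 0L)
    stop("count matrix contains no somatic columns")
  if (is.null(somatic_sum_max)) {
    if (is.null(n_total_samples)) n_total_samples <- ncol(cm$counts) + 1L
    somatic_sum_max <- n_total_samples
  }
  testis <- cm$counts[, testis_col]
  som <- cm$counts[, somatic_cols, drop = FALSE]
  som_sum <- rowSums(som)
  som_max <- apply(som, 1L, max)
  labels <- rep("other", nrow(cm$counts))
  testis_only <- som_sum < somatic_sum_max & testis > testis_min
  soma_and_testis <- !testis_only &
    testis >= expressed_min & som_max >= expressed_min
  labels[soma_and_testis] <- "soma_and_testis"
  labels[testis_only] <- "testis_only"
  stats::setNames(labels, rownames(cm$counts))
}

#' Summarise cluster counts per expression label
#'
#' @param labels Labels from [classify_clusters()].
#' @return data.frame with one row per label and cluster counts; rows sum
#'   to the total number of clusters.
#' @export
expression_accounting <- function(labels) {
  lv <- c("testis_only", "soma_and_testis", "other")
  tab <- table(factor(labels, levels = lv))
  data.frame(label = lv, n_clusters = as.integer(tab),
             fraction = as.numeric(tab) / max(1L, length(labels)))
}
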