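## End-to-end orchestration: prefilter -> map -> merge -> reference
## filters -> quantify -> classify -> base statistics -> TE annotation ->
## differential expression, with TSV/BED artifacts.

#' Default pipeline parameters
#'
#' The reference defaults: 25-32 nt length window, 10-read floors, 1 kb
#' merge distance, 0.1 oxidized/untreated ratio, testis > 50 /
#' expressed >= 10 classification thresholds, fold change > 4 with
#' p < 0.05 for differential expression, 90% TE identity.
#'
#' @return Named list of parameters.
#' @export
pipeline_params <- function() {
  list(min_len = 25L, max_len = 32L, min_count = 10, merge_distance = 1000L,
       min_ox_ratio = 0.1, stranded = FALSE, testis_min = 50,
       expressed_min = 10, lfc_min = 2, p_max = 0.05, min_identity = 0.90,
       index_k = 25L)
}

## reads (collapsed, prefiltered) whose placements overlap the reference
reads_on_reference <- function(reads, reference, index) {
  aln <- map_reads(reads, index)
  if (length(aln) == 0L) return(reads[0, , drop = FALSE])
  ov <- GenomicRanges::findOverlaps(aln, reference, ignore.strand = TRUE)
  keep_keys <- unique(paste(S4Vectors::mcols(aln)$sample_id,
                            S4Vectors::mcols(aln)$sequence)[
                              S4Vectors::queryHits(ov)])
  reads[paste(reads$sample_id, reads$sequence) %in% keep_keys, ,
        drop = FALSE]
}

#' Run the full piRNA-cluster pipeline
#'
#' @param genome Named DNAStringSet.
#' @param reads Collapsed read data.frame covering all samples.
#' @param sample_sheet Sample sheet data.frame.
#' @param mirna,trna Optional contaminant reference sequence sets.
#' @param mask Optional repeat-mask GRanges.
#' @param te_library Optional TE library data.frame
#'   (see [read_te_library()]).
#' @param genes Optional gene GRanges for proximity annotation.
#' @param group_a,group_b Group labels compared by differential
#'   expression (defaults: the groups of the `somatic_control` and
#'   `tumor` samples).
#' @param params Parameter list (see [pipeline_params()]); entries
#'   override the defaults.
#' @param out_dir Optional output directory for BED/TSV artifacts.
#' @return list with `reference` (preliminary/final cluster sets and
#'   reference counts), `counts`, `labels`, `accounting`, `base_stats`,
#'   `te` (hits, enrichment, fraction, miRNA QC), `de`, `de_summary`,
#'   `nearest_genes`, `params`.
#' @export
run_pipeline <- function(genome, reads, sample_sheet,
                         mirna = NULL, trna = NULL, mask = NULL,
                         te_library = NULL, genes = NULL,
                         group_a = NULL, group_b = NULL,
                         params = list(), out_dir = NULL) {
  p <- utils::modifyList(pipeline_params(), params)
  sheet <- validate_sample_sheet(sample_sheet)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  index <- stage("exact_mapper", build_index(genome, k = p$index_k))

  ox_id <- sheet$sample_id[sheet$role == "oxidized_testis"]
  testis_id <- sheet$sample_id[sheet$role == "testis"]
  ox_reads <- reads[reads$sample_id == ox_id, , drop = FALSE]
  testis_reads <- reads[reads$sample_id == testis_id, , drop = FALSE]
  if (nrow(ox_reads) == 0L)
    stop("pipeline stage 'cluster_reference' failed: no reads for the ",
         "oxidized_testis sample", call. = FALSE)

  ref <- stage("cluster_reference",
               build_reference(ox_reads, testis_reads, index,
                               mirna = mirna, trna = trna, mask = mask,
                               merge_distance = p$merge_distance,
                               min_count = p$min_count,
                               min_ox_ratio = p$min_ox_ratio,
                               stranded = p$stranded))

  quant_sheet <- sheet[sheet$role != "oxidized_testis", , drop = FALSE]
  quant_reads <- reads[reads$sample_id %in% quant_sheet$sample_id, ,
                       drop = FALSE]
  quant_reads <- stage("prefilter", {
    parts <- lapply(split(quant_reads, quant_reads$sample_id),
                    function(r) prefilter_reads(r, mirna, trna,
                                                p$min_len, p$max_len)$reads)
    do.call(rbind, parts)
  })
  cm <- stage("quantify_classify",
              quantify(quant_reads, ref$final, index, quant_sheet))
  labels <- stage("quantify_classify",
                  classify_clusters(cm, testis_min = p$testis_min,
                                    expressed_min = p$expressed_min,
                                    n_total_samples = nrow(sheet)))
  accounting <- expression_accounting(labels)

  ## base statistics per sample, on reads mapping inside the reference
  base_stats <- stage("base_stats", {
    mapped <- reads_on_reference(quant_reads, ref$final, index)
    parts <- lapply(split(mapped, mapped$sample_id), function(r) {
      comp <- base_composition(r)
      pr_a <- pathway_ratio(r, "10A")
      pr_g <- pathway_ratio(r, "10G")
      data.frame(sample_id = r$sample_id[1L],
                 u1 = comp$proportion[comp$position == 1 & comp$base == "U"],
                 a10 = comp$proportion[comp$position == 10 &
                                         comp$base == "A"],
                 ratio_10A = pr_a$ratio, ratio_10G = pr_g$ratio)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })

  te <- NULL
  if (!is.null(te_library)) {
    te <- stage("te_annotation", {
      seqs <- extract_cluster_seqs(ref$final, genome)
      hits <- match_clusters_to_tes(seqs, te_library,
                                    min_identity = p$min_identity)
      enr <- if (nrow(hits)) te_class_enrichment(hits, te_library) else NULL
      qc <- if (!is.null(mirna)) reference_mirna_qc(seqs, mirna) else NULL
      list(hits = hits, enrichment = enr,
           fraction_with_hit = fraction_clusters_with_hit(hits, ref$final),
           mirna_qc = qc)
    })
  }

  de <- NULL
  de_summary <- NULL
  groups <- stats::setNames(sheet$group, sheet$sample_id)
  if (is.null(group_a) && any(sheet$role == "somatic_control"))
    group_a <- sheet$group[sheet$role == "somatic_control"][1L]
  if (is.null(group_b) && any(sheet$role == "tumor"))
    group_b <- sheet$group[sheet$role == "tumor"][1L]
  if (!is.null(group_a) && !is.null(group_b)) {
    de <- stage("diffexp",
                differential_expression(cm, group_a, group_b,
                                        groups = groups,
                                        expressed_min = p$expressed_min,
                                        lfc_min = p$lfc_min,
                                        p_max = p$p_max))
    de_summary <- de_accounting(de)
  }

  nearest <- if (!is.null(genes)) nearest_gene(ref$final, genes) else NULL

  result <- list(reference = ref, counts = cm, labels = labels,
                 accounting = accounting, base_stats = base_stats,
                 te = te, de = de, de_summary = de_summary,
                 nearest_genes = nearest, params = p)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_bed(result$reference$preliminary,
            file.path(out_dir, "preliminary.bed"))
  write_bed(result$reference$final, file.path(out_dir, "final.bed"))
  counts <- data.frame(cluster_id = rownames(result$counts$counts),
                       result$counts$counts, check.names = FALSE)
  tsv(counts, "counts.tsv")
  tsv(data.frame(cluster_id = names(result$labels),
                 label = unname(result$labels)), "labels.tsv")
  tsv(result$base_stats, "basestats.tsv")
  if (!is.null(result$te)) {
    tsv(result$te$hits, "te_hits.tsv")
    if (!is.null(result$te$enrichment))
      tsv(result$te$enrichment, "te_enrichment.tsv")
  }
  if (!is.null(result$de)) tsv(result$de, "de.tsv")
  writeLines(paste(names(result$params),
                   vapply(result$params, format, ""), sep = "\t"),
             file.path(out_dir, "resolved_params.tsv"))
  invisible(out_dir)
}
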