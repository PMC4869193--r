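## Preliminary reference = mapped oxidized-testis positions merged when
## separated by <= 1 kb (bedtools mergeBed -d semantics); final reference
## = preliminary clusters surviving the count floor and the
## oxidized/non-oxidized ratio filter.

#' Merge mapped positions into clusters
#'
#' Intervals on one scaffold are merged transitively whenever the gap to
#' the next interval is at most `merge_distance` bp; book-ended and
#' overlapping intervals always merge.  Merging ignores strand by default
#' (mergeBed's default); `stranded = TRUE` merges per strand.
#'
#' @param alignments GRanges of read placements (or any intervals).
#' @param merge_distance Maximum gap in bp (default 1000).
#' @param stranded Merge per strand instead of strand-agnostically.
#' @return Preliminary cluster set: sorted, non-overlapping GRanges with
#'   ids as names and stage `"preliminary"`.
#' @export
merge_alignments <- function(alignments, merge_distance = 1000L,
                             stranded = FALSE) {
  if (merge_distance < 0) stop("merge_distance must be >= 0")
  if (length(alignments) == 0L) stop("no alignments to merge")
  merged <- GenomicRanges::reduce(alignments,
                                  min.gapwidth = merge_distance + 1L,
                                  ignore.strand = !stranded)
  if (!stranded) GenomicRanges::strand(merged) <- "*"
  as_cluster_set(merged, stage = "preliminary")
}

#' Count reads per cluster for one sample
#'
#' Each placement contributes to every cluster it overlaps (any overlap);
#' a multi-mapping read contributes its full collapsed count at every
#' placement (`count_mode = "full"`) or `count / n_placements` per
#' placement (`count_mode = "fractional"`).  Placements outside all
#' clusters are tallied as `unassigned`.
#'
#' @param alignments GRanges with `count` (and `sequence`) metadata.
#' @param clusters Cluster GRanges.
#' @param count_mode `"full"` or `"fractional"`.
#' @return Numeric vector of per-cluster counts (named by cluster id)
#'   with attribute `unassigned`.
#' @export
count_reads_per_cluster <- function(alignments, clusters,
                                    count_mode = c("full", "fractional")) {
  count_mode <- match.arg(count_mode)
  ids <- names(clusters)
  if (is.null(ids)) ids <- cluster_ids(clusters)
  counts <- stats::setNames(numeric(length(clusters)), ids)
  if (length(alignments) == 0L) {
    attr(counts, "unassigned") <- 0
    return(counts)
  }
  w <- as.numeric(S4Vectors::mcols(alignments)$count)
  if (count_mode == "fractional") {
    key <- paste(S4Vectors::mcols(alignments)$sample_id,
                 S4Vectors::mcols(alignments)$sequence)
    w <- w / as.numeric(table(key)[key])
  }
  ov <- GenomicRanges::findOverlaps(alignments, clusters, ignore.strand = TRUE)
  if (length(ov)) {
    agg <- tapply(w[S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov), sum)
    counts[as.integer(names(agg))] <- as.numeric(agg)
    names(counts) <- ids
  }
  outside <- setdiff(seq_along(alignments), unique(S4Vectors::queryHits(ov)))
  attr(counts, "unassigned") <- sum(w[outside])
  counts
}

#' Filter the preliminary reference into the final reference
#'
#' A cluster is retained iff it is not low-expressed in both the oxidized
#' and the untreated testis library (`ox < min_count AND testis <
#' min_count` excludes) and its oxidized/untreated count ratio is at
#' least `min_ox_ratio` (a low ratio marks oxidation-sensitive, i.e.
#' non-piRNA, RNA abundant in testis).  Edge rulings: `testis == 0` with
#' `ox > 0` gives ratio `+Inf` (ratio filter passes); `ox == 0` with
#' `testis > 0` gives ratio 0 (excluded).
#'
#' @param preliminary Preliminary cluster GRanges.
#' @param ox_counts,testis_counts Per-cluster counts on the preliminary
#'   reference for the oxidized-testis and untreated-testis libraries,
#'   in cluster order.
#' @param min_count Count floor (default 10).
#' @param min_ox_ratio Minimum oxidized/untreated ratio (default 0.1).
#' @return Final cluster set (stage `"final"`) with metadata columns
#'   `ox_count` and `testis_count`.
#' @export
filter_reference <- function(preliminary, ox_counts, testis_counts,
                             min_count = 10, min_ox_ratio = 0.1) {
  n <- length(preliminary)
  if (length(ox_counts) != n || length(testis_counts) != n)
    stop("counts must align with the preliminary clusters ",
         "(missing oxidized or testis sample?)")
  ox <- as.numeric(ox_counts)
  te <- as.numeric(testis_counts)
  pass_floor <- !(ox < min_count & te < min_count)
  ratio <- ifelse(te == 0, ifelse(ox > 0, Inf, NaN), ox / te)
  pass_ratio <- !is.nan(ratio) & ratio >= min_ox_ratio
  keep <- pass_floor & pass_ratio
  final <- preliminary[keep]
  S4Vectors::mcols(final)$ox_count <- ox[keep]
  S4Vectors::mcols(final)$testis_count <- te[keep]
  out <- as_cluster_set(final, stage = "final")
  attr(out, "n_excluded_floor") <- sum(!pass_floor)
  attr(out, "n_excluded_ratio") <- sum(pass_floor & !pass_ratio)
  out
}

#' Nearest gene for each cluster
#'
#' Distance is 0 for overlap; otherwise the gap in bp, signed positive
#' when the gene lies right of (downstream in scaffold coordinates) the
#' cluster and negative when left.  Ties go to the lower-coordinate gene.
#'
#' @param clusters Cluster GRanges.
#' @param genes Gene GRanges (e.g. from [read_bed()]); a `name` metadata
#'   column supplies gene ids.
#' @param flag_within Distance in bp for the proximity flag (default
#'   10000).
#' @return data.frame with `cluster_id`, `gene`, `distance`,
#'   `within_flag`.
#' @export
nearest_gene <- function(clusters, genes, flag_within = 10000L) {
  ids <- names(clusters)
  if (is.null(ids)) ids <- cluster_ids(clusters)
  if (length(genes) == 0L) {
    return(data.frame(cluster_id = ids, gene = NA_character_,
                      distance = NA_real_, within_flag = NA))
  }
  gene_ids <- S4Vectors::mcols(genes)$name
  if (is.null(gene_ids)) gene_ids <- cluster_ids(genes)
  out <- data.frame(cluster_id = ids, gene = NA_character_,
                    distance = NA_real_, within_flag = NA)
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    same <- as.character(GenomicRanges::seqnames(genes)) ==
      as.character(GenomicRanges::seqnames(cl))
    if (!any(same)) next
    g <- genes[same]
    gi <- gene_ids[same]
    d <- GenomicRanges::distance(cl, g, ignore.strand = TRUE)
    best <- which(d == min(d))
    best <- best[which.min(GenomicRanges::start(g)[best])]
    dist <- d[best]
    if (dist > 0 && GenomicRanges::start(g)[best] < GenomicRanges::start(cl))
      dist <- -dist
    out$gene[i] <- gi[best]
    out$distance[i] <- dist
    out$within_flag[i] <- abs(dist) <= flag_within
  }
  out
}

#' Build a piRNA cluster reference from oxidized and untreated testis reads
#'
#' Convenience wrapper running prefilter (with the low-abundance floor on
#' the oxidized library only), mapping, merging and reference filtering.
#'
#' @param ox_reads,testis_reads Collapsed read data.frames.
#' @param index `genome_index` over the target genome.
#' @param mirna,trna Optional contaminant reference sets.
#' @param mask Optional repeat mask GRanges.
#' @param merge_distance,min_count,min_ox_ratio,stranded Reference
#'   parameters (defaults 1000 bp, 10 reads, 0.1, strand-agnostic).
#' @return list with `preliminary`, `final`, `ox_counts`, `testis_counts`.
#' @export
build_reference <- function(ox_reads, testis_reads, index,
                            mirna = NULL, trna = NULL, mask = NULL,
                            merge_distance = 1000L, min_count = 10,
                            min_ox_ratio = 0.1, stranded = FALSE) {
  ox <- prefilter_reads(ox_reads, mirna, trna, min_count = min_count)$reads
  te <- prefilter_reads(testis_reads, mirna, trna)$reads
  aln_ox <- map_reads(ox, index)
  aln_te <- map_reads(te, index)
  if (!is.null(mask)) {
    aln_ox <- exclude_by_repeat_mask(aln_ox, mask)
    aln_te <- exclude_by_repeat_mask(aln_te, mask)
  }
  if (length(aln_ox) == 0L) stop("no oxidized-testis alignments survive")
  preliminary <- merge_alignments(aln_ox, merge_distance, stranded)
  ox_counts <- count_reads_per_cluster(aln_ox, preliminary)
  testis_counts <- count_reads_per_cluster(aln_te, preliminary)
  final <- filter_reference(preliminary, ox_counts, testis_counts,
                            min_count, min_ox_ratio)
  list(preliminary = preliminary, final = final,
       ox_counts = ox_counts, testis_counts = testis_counts)
}
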