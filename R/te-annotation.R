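## Matching cluster sequences against a classed transposable-element
## library and testing per-class enrichment of hit TEs against the class
## make-up of the whole library.

#' Read a TE library FASTA with class-annotated headers
#'
#' Header dialect `>te_id#class` (e.g. `>Tx1#LINE`); a missing class
#' token yields class `unknown`.
#'
#' @param path FASTA path.
#' @return data.frame with `te_id`, `class`, `sequence`.
#' @export
read_te_library <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  hdr <- sub("\\s.*$", "", names(seqs))
  te_id <- sub("#.*$", "", hdr)
  class <- ifelse(grepl("#", hdr), sub("^[^#]*#", "", hdr), "unknown")
  if (anyDuplicated(te_id)) stop("duplicate te_ids in TE library")
  data.frame(te_id = te_id, class = class,
             sequence = normalize_seq(as.character(seqs)),
             stringsAsFactors = FALSE)
}

#' Extract cluster sequences from the genome
#'
#' @param clusters Cluster GRanges.
#' @param genome Named DNAStringSet.
#' @return Named character vector of cluster sequences.
#' @export
extract_cluster_seqs <- function(clusters, genome) {
  chr <- as.character(genome)
  sc <- as.character(GenomicRanges::seqnames(clusters))
  bad <- setdiff(unique(sc), names(chr))
  if (length(bad)) stop("clusters on scaffolds absent from genome: ",
                        paste(bad, collapse = ", "))
  seqs <- substring(chr[sc], GenomicRanges::start(clusters),
                    GenomicRanges::end(clusters))
  ids <- names(clusters)
  if (is.null(ids)) ids <- cluster_ids(clusters)
  stats::setNames(seqs, ids)
}

#' Read 12-column tabular alignment hits (BLAST outfmt 6)
#'
#' @param path Tab-separated file with the standard 12 columns.
#' @return data.frame with `query`, `subject`, `identity` (fraction),
#'   `length`, `score`.
#' @export
read_blast_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad)) stop("malformed tabular row(s): ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  data.frame(
    query = vapply(fields, `[[`, "", 1L),
    subject = vapply(fields, `[[`, "", 2L),
    identity = as.numeric(vapply(fields, `[[`, "", 3L)) / 100,
    length = as.integer(vapply(fields, `[[`, "", 4L)),
    score = as.numeric(vapply(fields, `[[`, "", 12L)),
    stringsAsFactors = FALSE)
}

## greedy ungapped extension of one exact seed; returns c(length, matches)
extend_seed <- function(q, s, qpos, spos, seed_len, max_mismatch_frac) {
  len <- seed_len
  mism <- 0L
  ## extend right
  i <- qpos + seed_len
  j <- spos + seed_len
  while (i <= length(q) && j <= length(s)) {
    m <- mism + as.integer(q[i] != s[j])
    if (m / (len + 1L) > max_mismatch_frac) break
    mism <- m; len <- len + 1L; i <- i + 1L; j <- j + 1L
  }
  ## extend left
  i <- qpos - 1L
  j <- spos - 1L
  left <- 0L
  while (i >= 1L && j >= 1L) {
    m <- mism + as.integer(q[i] != s[j])
    if (m / (len + 1L) > max_mismatch_frac) break
    mism <- m; len <- len + 1L; left <- left + 1L; i <- i - 1L; j <- j - 1L
  }
  c(start = qpos - left, length = len, matches = len - mism)
}

## all seed-extended local hits of one query against one subject
ungapped_hits <- function(qseq, sseq, seed_len, min_identity) {
  q <- strsplit(qseq, "", fixed = TRUE)[[1L]]
  s <- strsplit(sseq, "", fixed = TRUE)[[1L]]
  if (length(q) < seed_len || length(s) < seed_len) return(NULL)
  qpos <- seq_len(length(q) - seed_len + 1L)
  qk <- substring(qseq, qpos, qpos + seed_len - 1L)
  spos <- seq_len(length(s) - seed_len + 1L)
  sk <- substring(sseq, spos, spos + seed_len - 1L)
  sk_map <- split(spos, sk)
  covered <- integer(0)
  out <- list()
  max_mm <- 1 - min_identity
  for (qi in qpos) {
    if (qi %in% covered) next
    hits_s <- sk_map[[qk[qi]]]
    if (is.null(hits_s)) next
    for (sj in hits_s) {
      ext <- extend_seed(q, s, qi, sj, seed_len, max_mm)
      ident <- ext["matches"] / ext["length"]
      if (ident >= min_identity) {
        out[[length(out) + 1L]] <- ext
        covered <- union(covered,
                         seq(ext["start"], ext["start"] + ext["length"] - 1L))
        break
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Match cluster sequences against a TE library
#'
#' `engine = "internal"` runs a seeded ungapped matcher (exact 15-mer
#' seed, greedy extension in both directions stopping when the
#' accumulated mismatch fraction exceeds `1 - min_identity`), on both
#' strands.  It is a test-scale matcher, not a BLAST replacement:
#' for real genomes run BLAST externally and feed the tabular output via
#' `engine = "external"` / `hits`.
#'
#' @param cluster_seqs Named character vector (see
#'   [extract_cluster_seqs()]).
#' @param library TE library data.frame from [read_te_library()].
#' @param min_identity Identity threshold (fraction, default 0.90).
#' @param engine `"internal"` or `"external"`.
#' @param hits For `engine = "external"`: data.frame from
#'   [read_blast_tabular()] (or a path to one).
#' @param seed_len Internal engine seed length.
#' @param min_length Minimum alignment length reported (internal engine).
#' @return TE hit table: data.frame with `cluster_id`, `te_id`, `class`,
#'   `identity`, `length`, `score`; all rows satisfy the identity
#'   threshold.
#' @export
match_clusters_to_tes <- function(cluster_seqs, library,
                                  min_identity = 0.90,
                                  engine = c("internal", "external"),
                                  hits = NULL, seed_len = 15L,
                                  min_length = 30L) {
  engine <- match.arg(engine)
  empty <- data.frame(cluster_id = character(), te_id = character(),
                      class = character(), identity = numeric(),
                      length = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (engine == "external") {
    if (is.character(hits)) hits <- read_blast_tabular(hits)
    if (is.null(hits)) stop("engine='external' requires tabular hits")
    hits <- hits[hits$identity >= min_identity, , drop = FALSE]
    if (nrow(hits) == 0L) return(empty)
    cls <- library$class[match(hits$subject, library$te_id)]
    return(data.frame(cluster_id = hits$query, te_id = hits$subject,
                      class = cls, identity = hits$identity,
                      length = hits$length, score = hits$score,
                      stringsAsFactors = FALSE))
  }
  res <- list()
  for (ci in seq_along(cluster_seqs)) {
    cs <- cluster_seqs[[ci]]
    cid <- names(cluster_seqs)[ci]
    for (ti in seq_len(nrow(library))) {
      for (sseq in c(library$sequence[ti], revcomp(library$sequence[ti]))) {
        h <- ungapped_hits(cs, sseq, seed_len, min_identity)
        if (!is.null(h)) {
          h <- h[h[, "length"] >= min_length, , drop = FALSE]
          if (nrow(h) == 0L) next
          best <- h[which.max(h[, "matches"]), , drop = FALSE]
          res[[length(res) + 1L]] <- data.frame(
            cluster_id = cid, te_id = library$te_id[ti],
            class = library$class[ti],
            identity = best[, "matches"] / best[, "length"],
            length = unname(best[, "length"]),
            score = unname(best[, "matches"]),
            stringsAsFactors = FALSE)
          break  # one orientation per (cluster, TE) pair suffices
        }
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  ## keep the best hit per (cluster, TE) pair
  out <- out[order(out$cluster_id, out$te_id, -out$score), ]
  out[!duplicated(out[, c("cluster_id", "te_id")]), , drop = FALSE]
}

#' Per-class enrichment of hit TEs against the library
#'
#' The unit is the distinct TE: a TE hit by several clusters counts once.
#' For each class, the fraction of hit TEs in that class is compared with
#' the class fraction of the full library by a two-sample proportion test
#' (chi-square with continuity correction); two-sided p-values with
#' significance flags at 0.1 (*), 0.05 (**) and 0.01 (***).
#'
#' @param hits TE hit table from [match_clusters_to_tes()].
#' @param library TE library data.frame.
#' @return data.frame per class: `class`, `n_hit`, `n_library`,
#'   `proportion_hit`, `proportion_library`, `p_value`, `flag`.
#' @export
te_class_enrichment <- function(hits, library) {
  if (nrow(hits) == 0L) stop("no TE hits to test")
  hit_tes <- unique(hits[, c("te_id", "class")])
  bad <- setdiff(unique(hit_tes$class), unique(library$class))
  if (length(bad)) {
    warning("classes absent from library skipped: ",
            paste(bad, collapse = ", "))
    hit_tes <- hit_tes[!hit_tes$class %in% bad, , drop = FALSE]
  }
  n_hit <- nrow(hit_tes)
  n_lib <- nrow(library)
  classes <- sort(unique(library$class))
  rows <- lapply(classes, function(cl) {
    k_hit <- sum(hit_tes$class == cl)
    k_lib <- sum(library$class == cl)
    p <- tryCatch(
      suppressWarnings(stats::prop.test(c(k_hit, k_lib),
                                        c(n_hit, n_lib)))$p.value,
      error = function(e) NA_real_)
    data.frame(class = cl, n_hit = k_hit, n_library = k_lib,
               proportion_hit = k_hit / n_hit,
               proportion_library = k_lib / n_lib,
               p_value = p,
               flag = if (is.na(p)) "" else if (p < 0.01) "***"
                      else if (p < 0.05) "**" else if (p < 0.1) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of clusters with at least one TE hit
#'
#' @param hits TE hit table.
#' @param clusters Cluster GRanges (denominator).
#' @return Proportion in `[0, 1]`.
#' @export
fraction_clusters_with_hit <- function(hits, clusters) {
  if (length(clusters) == 0L) return(NA_real_)
  length(unique(hits$cluster_id)) / length(clusters)
}

#' miRNA contamination check of a cluster reference
#'
#' Reuses the sequence-set screen to ask whether any known miRNA hairpin
#' occurs inside a reference cluster sequence (either strand).
#'
#' @param cluster_seqs Named character vector of cluster sequences.
#' @param mirna Hairpin sequences (DNAStringSet or character).
#' @return list with `clean` (TRUE when no hairpin overlaps the
#'   reference) and `n_hairpins_found`.
#' @export
reference_mirna_qc <- function(cluster_seqs, mirna) {
  hp <- data.frame(sequence = normalize_seq(as.character(mirna)),
                   count = 1L, sample_id = "hairpins",
                   stringsAsFactors = FALSE)
  kept <- exclude_by_sequence_set(hp, cluster_seqs)
  n_found <- nrow(hp) - nrow(kept)
  list(clean = n_found == 0L, n_hairpins_found = n_found)
}
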