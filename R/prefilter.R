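## Read-level exclusion cascade applied to every library before mapping:
## length window -> known miRNA removal -> known tRNA removal ->
## (after mapping) repeat-mask exclusion -> low-abundance floor.

#' Keep reads inside a length window
#'
#' piRNAs are 25-32 nt; the window excludes miRNA-sized reads below and
#' degradation products above.  Both bounds are inclusive.
#'
#' @param reads Collapsed read data.frame.
#' @param min_len,max_len Inclusive length bounds (defaults 25 and 32).
#' @return Filtered read data.frame.
#' @export
length_filter <- function(reads, min_len = 25L, max_len = 32L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  len <- nchar(reads$sequence)
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Remove reads matching a reference sequence set (miRNA/tRNA removal)
#'
#' A read is removed when its sequence, or its reverse complement, occurs
#' as an exact substring of any reference sequence (`mode = "substring"`,
#' the default, used for hairpin and tRNA screens), or equals a reference
#' sequence exactly (`mode = "exact"`).  `max_mismatch = 1` enables a
#' Hamming-distance-tolerant screen (off by default).
#'
#' @param reads Collapsed read data.frame.
#' @param reference_seqs DNAStringSet or character vector of reference
#'   sequences (miRNA hairpins, tRNAs, ...).
#' @param mode `"substring"` or `"exact"`.
#' @param max_mismatch Allowed mismatches (0 or 1) in substring mode.
#' @return Filtered read data.frame.
#' @export
exclude_by_sequence_set <- function(reads,
                                    reference_seqs,
                                    mode = c("substring", "exact"),
                                    max_mismatch = 0L) {
  mode <- match.arg(mode)
  refs <- normalize_seq(as.character(reference_seqs))
  if (length(refs) == 0L) {
    warning("empty reference set: no reads excluded")
    return(reads)
  }
  if (nrow(reads) == 0L) return(reads)
  seqs <- reads$sequence
  rc <- revcomp(seqs)
  if (mode == "exact") {
    hit <- seqs %in% refs | rc %in% refs
  } else if (max_mismatch == 0L) {
    ## exact substring on either strand; the separator cannot occur in
    ## the DNA alphabet, so matches never span two references
    subject <- paste(refs, collapse = "|")
    hit <- vapply(seqs, grepl, TRUE, x = subject, fixed = TRUE,
                  USE.NAMES = FALSE) |
      vapply(rc, grepl, TRUE, x = subject, fixed = TRUE, USE.NAMES = FALSE)
  } else {
    hit <- hamming_window_hit(seqs, refs, max_mismatch) |
      hamming_window_hit(rc, refs, max_mismatch)
  }
  reads[!hit, , drop = FALSE]
}

## TRUE for each query with >= 1 reference window within `max_mismatch`
## Hamming distance.  Small-scale helper for the tolerant screen.
hamming_window_hit <- function(queries, refs, max_mismatch) {
  out <- logical(length(queries))
  by_len <- split(seq_along(queries), nchar(queries))
  for (len_chr in names(by_len)) {
    len <- as.integer(len_chr)
    wins <- unlist(lapply(refs, function(r) {
      n <- nchar(r)
      if (n < len) return(character())
      substring(r, seq_len(n - len + 1L), seq_len(n - len + 1L) + len - 1L)
    }), use.names = FALSE)
    if (!length(wins)) next
    wmat <- matrix(unlist(strsplit(wins, "", fixed = TRUE)),
                   nrow = len)
    idx <- by_len[[len_chr]]
    qmat <- matrix(unlist(strsplit(queries[idx], "", fixed = TRUE)),
                   nrow = len)
    for (j in seq_along(idx)) {
      mism <- colSums(wmat != qmat[, j])
      if (any(mism <= max_mismatch)) out[idx[j]] <- TRUE
    }
  }
  out
}

#' Parse a RepeatMasker .out annotation file
#'
#' @param path RepeatMasker `.out` file (3 header lines, whitespace
#'   separated columns).
#' @return GRanges with metadata columns `repeat_name` and `repeat_class`
#'   (the class token before any "/" subfamily).
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  ## header block: two column-name lines and a blank line, tolerate absence
  body <- lines[nzchar(lines) & !grepl("^(SW|score|perc)", lines)]
  if (length(body) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(body, "\\s+")
  ok <- lengths(fields) >= 11L
  if (!all(ok)) stop("malformed RepeatMasker row(s): ",
                     paste(which(!ok), collapse = ", "))
  scaffold <- vapply(fields, `[[`, "", 5L)
  start1 <- as.integer(vapply(fields, `[[`, "", 6L))
  end <- as.integer(vapply(fields, `[[`, "", 7L))
  strand <- vapply(fields, `[[`, "", 9L)
  strand <- ifelse(strand == "C", "-", "+")
  rep_name <- vapply(fields, `[[`, "", 10L)
  rep_class <- vapply(fields, `[[`, "", 11L)
  gr <- GenomicRanges::GRanges(
    seqnames = scaffold,
    ranges = IRanges::IRanges(start = start1, end = end),
    strand = strand)
  S4Vectors::mcols(gr)$repeat_name <- rep_name
  S4Vectors::mcols(gr)$repeat_class <- sub("/.*$", "", rep_class)
  gr
}

#' Remove alignments overlapping excluded repeat classes
#'
#' Alignments with any overlap (>= 1 bp) of a mask interval whose class is
#' in `exclude_classes` are removed.  Transposon-derived classes (LTR,
#' LINE, SINE, DNA, RC) are retained: piRNA clusters are expected to be
#' transposon-rich, only residual structural RNAs and simple repeats are
#' screened out.  Unknown class strings are retained with a warning.
#'
#' @param alignments GRanges of read placements.
#' @param mask GRanges with a `repeat_class` metadata column (e.g. from
#'   [read_repeatmasker_out()]), or a plain GRanges treated as all-excluded.
#' @param exclude_classes Repeat classes to exclude.
#' @return Filtered alignments GRanges.
#' @export
exclude_by_repeat_mask <- function(alignments, mask,
                                   exclude_classes = c("tRNA", "rRNA",
                                                       "Simple_repeat",
                                                       "Low_complexity")) {
  if (length(mask) == 0L) return(alignments)
  keep_classes <- c("LTR", "LINE", "SINE", "DNA", "RC", "Retroposon",
                    "Satellite", "snRNA", "srpRNA", "scRNA", "Unknown")
  if (!is.null(S4Vectors::mcols(mask)$repeat_class)) {
    cls <- S4Vectors::mcols(mask)$repeat_class
    unknown <- setdiff(unique(cls), c(exclude_classes, keep_classes))
    if (length(unknown))
      warning("unrecognised repeat classes retained: ",
              paste(unknown, collapse = ", "))
    mask <- mask[cls %in% exclude_classes]
  }
  if (length(mask) == 0L) return(alignments)
  hits <- GenomicRanges::findOverlaps(alignments, mask, ignore.strand = TRUE)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) alignments[-drop] else alignments
}

#' Remove low-abundance unique sequences
#'
#' Unique sequences sequenced fewer than `min_count` times are dropped.
#' Applied to the oxidized library before reference construction.
#'
#' @param reads Collapsed read data.frame.
#' @param min_count Minimum collapsed count to keep (default 10).
#' @return Filtered read data.frame.
#' @export
low_abundance_filter <- function(reads, min_count = 10L) {
  if (min_count < 1L) stop("min_count must be >= 1")
  reads[reads$count >= min_count, , drop = FALSE]
}

#' Run the sequence-level prefilter cascade with accounting
#'
#' Applies, in order: length window, miRNA exclusion, tRNA exclusion and
#' (optionally) the low-abundance floor, recording unique-sequence and
#' read totals removed at each stage.  The repeat-mask stage operates on
#' mapped positions and is applied separately (see
#' [exclude_by_repeat_mask()]).
#'
#' @param reads Collapsed read data.frame.
#' @param mirna,trna Optional reference sequence sets.
#' @param min_len,max_len Length window.
#' @param min_count Low-abundance floor; `NULL` skips the stage.
#' @return list with elements `reads` (filtered) and `report` (data.frame
#'   with per-stage removals; removals sum to input minus output).
#' @export
prefilter_reads <- function(reads, mirna = NULL, trna = NULL,
                            min_len = 25L, max_len = 32L,
                            min_count = NULL) {
  stages <- list()
  tally <- function(x) c(unique = nrow(x), reads = sum(x$count))
  input <- tally(reads)
  cur <- reads

  step <- function(name, new) {
    prev <- tally(cur)
    now <- tally(new)
    stages[[name]] <<- data.frame(
      stage = name,
      unique_removed = unname(prev["unique"] - now["unique"]),
      reads_removed = unname(prev["reads"] - now["reads"]))
    cur <<- new
  }

  step("length", length_filter(cur, min_len, max_len))
  if (!is.null(mirna)) step("mirna", exclude_by_sequence_set(cur, mirna))
  if (!is.null(trna)) step("trna", exclude_by_sequence_set(cur, trna))
  if (!is.null(min_count)) {
    step("low_abundance", low_abundance_filter(cur, min_count))
  }
  out <- tally(cur)
  report <- do.call(rbind, stages)
  rownames(report) <- NULL
  report <- rbind(report,
                  data.frame(stage = c("input", "output"),
                             unique_removed = NA_integer_,
                             reads_removed = NA_integer_))
  report$unique_total <- c(rep(NA, nrow(report) - 2L), input["unique"],
                           out["unique"])
  report$reads_total <- c(rep(NA, nrow(report) - 2L), input["reads"],
                          out["reads"])
  list(reads = cur, report = report)
}
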