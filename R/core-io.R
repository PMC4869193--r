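## Shared conventions
##
## Reads are plain data.frames with columns `sequence` (DNA alphabet,
## upper case, U converted to T), `count` (collapsed read count) and
## `sample_id`.  Genomic intervals are GRanges (1-based, closed) inside
## the package; all BED input/output is converted to/from the 0-based
## half-open BED convention at the file boundary.  Cluster identifiers
## are BED-style "scaffold:start-end" strings (0-based start) so the id
## printed in a BED name column matches the coordinates on the same line.

#' Read a genome FASTA file
#'
#' Scaffold names are taken from the header up to the first whitespace.
#' Sequences are upper-cased and `U` is converted to `T` so that all
#' downstream sequence comparison happens in the DNA alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one entry per scaffold.
#' @export
read_fasta_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm)) {
    stop("duplicate scaffold names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- chartr("u", "t", toupper(as.character(raw)))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- nm
  Biostrings::DNAStringSet(seqs)
}

normalize_seq <- function(x) chartr("U", "T", toupper(x))

#' Collapse read sequences to unique sequences with counts
#'
#' Identical sequences (case-insensitive, U == T) within one sample are
#' merged and their counts summed.  Collapsing is order-independent.
#'
#' @param sequences Character vector of read sequences.
#' @param counts Integer vector of per-sequence counts (default all 1).
#' @param sample_id Sample identifier attached to every collapsed read.
#' @return data.frame with columns `sequence`, `count`, `sample_id`.
#' @export
collapse_reads <- function(sequences, counts = NULL, sample_id = "sample") {
  if (is.null(counts)) counts <- rep(1L, length(sequences))
  stopifnot(length(counts) == length(sequences))
  if (length(sequences) == 0L) {
    return(data.frame(sequence = character(), count = integer(),
                      sample_id = character(), stringsAsFactors = FALSE))
  }
  dt <- data.table::data.table(sequence = normalize_seq(sequences),
                               count = as.integer(counts))
  out <- dt[, list(count = sum(count)), by = "sequence"]
  data.table::setorder(out, sequence)
  data.frame(sequence = out$sequence, count = out$count,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Read a small-RNA read file (FASTQ, FASTA, or count-collapsed FASTA)
#'
#' In the collapsed-FASTA dialect a trailing `-<count>` on the header
#' (e.g. `>seq1-17`) carries the read count; all other records count 1.
#' Reads are collapsed per sample on return.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @param sample_id Sample identifier for the returned reads.
#' @return data.frame of collapsed reads (see [collapse_reads()]).
#' @export
read_small_rna <- function(path, format = c("auto", "fasta", "fastq"),
                           sample_id = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("malformed ", format, " file ", path, ": ",
                             conditionMessage(e)))
  counts <- rep(1L, length(raw))
  if (format == "fasta") {
    hdr <- sub("\\s.*$", "", names(raw))
    m <- regmatches(hdr, regexpr("-([0-9]+)$", hdr))
    has <- lengths(regmatches(hdr, gregexpr("-[0-9]+$", hdr))) > 0
    if (any(has)) counts[has] <- as.integer(sub("^-", "", m))
  }
  collapse_reads(as.character(raw), counts, sample_id = sample_id)
}

#' Write collapsed reads as count-annotated FASTA
#'
#' Emits the collapsed-FASTA dialect read back by [read_small_rna()]:
#' one record per unique sequence with header `>seq<i>-<count>`.
#'
#' @param reads Collapsed read data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_collapsed_fasta <- function(reads, path) {
  hdr <- sprintf(">seq%d-%d", seq_len(nrow(reads)), reads$count)
  writeLines(as.vector(rbind(hdr, reads$sequence)), path)
  invisible(path)
}

#' Stable cluster identifiers
#'
#' BED-style `scaffold:start-end` ids with a 0-based start, matching the
#' coordinates the same cluster gets in BED output.
#'
#' @param gr A GRanges object.
#' @return Character vector of ids.
#' @export
cluster_ids <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

#' Build a cluster set from a GRanges object
#'
#' Sorts lexicographically by scaffold then start, assigns stable ids and
#' records the reference stage (`preliminary` or `final`).
#'
#' @param gr GRanges of cluster intervals.
#' @param stage `"preliminary"` or `"final"`.
#' @return GRanges with names set to cluster ids and a `stage` attribute
#'   in its metadata.
#' @export
as_cluster_set <- function(gr, stage = c("preliminary", "final")) {
  stage <- match.arg(stage)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  names(gr) <- cluster_ids(gr)
  S4Vectors::metadata(gr)$stage <- stage
  gr
}

#' Write a cluster set as BED6
#'
#' Coordinates are written 0-based half-open; the name column carries the
#' cluster id, the score column is `.`.
#'
#' @param clusters GRanges (names used as BED names when present).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bed <- function(clusters, path) {
  st <- GenomicRanges::start(clusters) - 1L
  en <- GenomicRanges::end(clusters)
  if (any(st < 0L) || any(st >= en)) stop("invalid interval coordinates")
  nm <- names(clusters)
  if (is.null(nm)) nm <- cluster_ids(clusters)
  strand <- as.character(GenomicRanges::strand(clusters))
  strand[strand == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(clusters)),
                 st, en, nm, ".", strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into a GRanges object
#'
#' @param path BED3+ file; track/comment lines are skipped.
#' @param one_based Set `TRUE` for the 1-based inclusive dialect; starts
#'   are then shifted by -1 on read.
#' @return GRanges with `name` metadata column when present.
#' @export
read_bed <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(lengths(fields))
  if (nf < 3L) stop("BED file needs at least 3 columns: ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  if (one_based) start0 <- start0 - 1L
  if (any(is.na(start0)) || any(is.na(end))) stop("non-numeric BED coordinates")
  if (any(start0 >= end)) stop("BED interval with start >= end in ", path)
  strand <- if (nf >= 6L) vapply(fields, `[[`, "", 6L) else rep(".", length(chrom))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end),
    strand = strand)
  if (nf >= 4L) {
    S4Vectors::mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
    names(gr) <- S4Vectors::mcols(gr)$name
  }
  gr
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `role`, `group`.  Roles come
#' from the vocabulary `oxidized_testis`, `testis`, `ovary`,
#' `somatic_control`, `tumor`.
#'
#' @param path TSV file path.
#' @param require_reference_pair Require exactly one `oxidized_testis` and
#'   one `testis` sample (needed for reference construction).
#' @return data.frame with validated columns.
#' @export
read_sample_sheet <- function(path, require_reference_pair = TRUE) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet, require_reference_pair)
}

#' @rdname read_sample_sheet
#' @param sheet A data.frame to validate in place of a file.
#' @export
validate_sample_sheet <- function(sheet, require_reference_pair = TRUE) {
  need <- c("sample_id", "role", "group")
  if (!all(need %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  roles <- c("oxidized_testis", "testis", "ovary", "somatic_control", "tumor")
  bad <- setdiff(unique(sheet$role), roles)
  if (length(bad))
    stop("unknown sample roles: ", paste(bad, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_ids in sample sheet")
  if (require_reference_pair) {
    if (sum(sheet$role == "oxidized_testis") != 1L ||
        sum(sheet$role == "testis") != 1L)
      stop("reference construction requires exactly one oxidized_testis ",
           "and one testis sample")
  }
  sheet
}

#' Construct a cluster count matrix
#'
#' A light container for the clusters x samples count table together with
#' the per-sample role labels.
#'
#' @param counts Integer matrix, rows = cluster ids, cols = sample ids.
#' @param roles Named character vector mapping sample id to role.
#' @return Object of class `pirna_counts`.
#' @export
count_matrix <- function(counts, roles) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have cluster ids as rownames and sample ids as colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  missing <- setdiff(colnames(counts), names(roles))
  if (length(missing))
    stop("roles missing for samples: ", paste(missing, collapse = ", "))
  structure(list(counts = counts, roles = roles[colnames(counts)]),
            class = "pirna_counts")
}

#' @export
print.pirna_counts <- function(x, ...) {
  cat(sprintf("pirna_counts: %d clusters x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("roles:", paste(sprintf("%s=%s", names(x$roles), x$roles),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Reverse complement of character sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
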