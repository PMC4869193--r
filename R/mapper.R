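## Exact, all-occurrence placement of 25-32 nt reads on a genome:
## a k-mer postings index (k = minimum read length) seeds candidate
## positions, each verified by full-length comparison, so every reported
## placement is an exact match and every exact match is reported.

#' Build a k-mer postings index over a genome
#'
#' Postings cover the forward strand only; reverse-strand placements are
#' found by querying a read's reverse complement.  k-mers containing `N`
#' are absent from the index.
#'
#' @param genome Named DNAStringSet (see [read_fasta_genome()]).
#' @param k Seed length; must not exceed the minimum read length
#'   (default 25, the shortest piRNA retained by the prefilter).
#' @return Object of class `genome_index`.
#' @export
build_index <- function(genome, k = 25L) {
  k <- as.integer(k)
  if (k < 10L) stop("k < 10 would produce a pathologically dense index")
  chr <- as.character(genome)
  postings <- data.table::rbindlist(lapply(names(chr), function(sc) {
    s <- chr[[sc]]
    n <- nchar(s)
    if (n < k) return(NULL)
    pos <- seq_len(n - k + 1L)
    km <- substring(s, pos, pos + k - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    data.table::data.table(kmer = km[keep], scaffold = sc, pos = pos[keep])
  }))
  if (nrow(postings) == 0L) stop("genome shorter than k everywhere")
  data.table::setkey(postings, kmer)
  structure(list(k = k, postings = postings, genome = chr),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index: k=%d, %d postings, %d scaffold(s)\n",
              x$k, nrow(x$postings), length(x$genome)))
  invisible(x)
}

## candidate placements of `seqs` (all same orientation) via seed lookup
## + full-length verification; returns data.table(sequence, scaffold, start)
seed_and_verify <- function(seqs, index) {
  k <- index$k
  dt <- data.table::data.table(sequence = seqs,
                               kmer = substr(seqs, 1L, k))
  cand <- index$postings[dt, on = "kmer", allow.cartesian = TRUE,
                         nomatch = NULL]
  if (nrow(cand) == 0L)
    return(data.table::data.table(sequence = character(),
                                  scaffold = character(), start = integer()))
  len <- nchar(cand$sequence)
  full <- substring(index$genome[cand$scaffold], cand$pos,
                    cand$pos + len - 1L)
  cand <- cand[full == cand$sequence]
  cand[, list(sequence, scaffold, start = pos)]
}

#' Map reads exactly to the genome, reporting all placements
#'
#' Every exact full-length occurrence on either strand is reported; a
#' read matching both strands at the same locus (palindrome) is reported
#' once per strand.  Reads containing `N` never match.  Reads with zero
#' placements are dropped and tallied in the result's metadata.
#'
#' @param reads Collapsed read data.frame.
#' @param index `genome_index` from [build_index()].
#' @param max_hits Optional cap on placements per read; reads exceeding it
#'   are dropped (default unlimited).
#' @return GRanges of placements with metadata columns `sequence`,
#'   `count`, `sample_id`; `S4Vectors::metadata()` holds `n_unmapped`
#'   (unique unmapped sequences) and `unmapped_reads` (their read total).
#' @export
map_reads <- function(reads, index, max_hits = Inf) {
  stopifnot(inherits(index, "genome_index"))
  if (nrow(reads) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr) <- list(n_unmapped = 0L, unmapped_reads = 0L)
    return(gr)
  }
  short <- nchar(reads$sequence) < index$k
  if (any(short))
    stop("reads shorter than seed length k=", index$k, ": ",
         paste(utils::head(reads$sequence[short], 5L), collapse = ", "))
  useq <- unique(reads$sequence)
  has_n <- grepl("N", useq, fixed = TRUE)
  fwd <- seed_and_verify(useq[!has_n], index)
  if (nrow(fwd)) fwd[, strand := "+"]
  rcs <- revcomp(useq[!has_n])
  rev <- seed_and_verify(rcs, index)
  if (nrow(rev)) {
    ## rev$sequence is the reverse complement; map back to the read
    back <- stats::setNames(useq[!has_n], rcs)
    rev[, sequence := unname(back[sequence])]
    rev[, strand := "-"]
  }
  hits <- data.table::rbindlist(list(fwd, rev), fill = TRUE)
  if (is.finite(max_hits) && nrow(hits)) {
    nh <- hits[, .N, by = "sequence"]
    keep <- nh$sequence[nh$N <= max_hits]
    hits <- hits[sequence %in% keep]
  }
  mapped_seqs <- unique(hits$sequence)
  unmapped <- setdiff(useq, mapped_seqs)
  rdt <- data.table::as.data.table(reads)
  placed <- rdt[hits, on = "sequence", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(placed) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = placed$scaffold,
      ranges = IRanges::IRanges(start = placed$start,
                                width = nchar(placed$sequence)),
      strand = placed$strand)
    S4Vectors::mcols(gr)$sequence <- placed$sequence
    S4Vectors::mcols(gr)$count <- placed$count
    S4Vectors::mcols(gr)$sample_id <- placed$sample_id
    gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr))]
  }
  S4Vectors::metadata(gr) <- list(
    n_unmapped = length(unmapped),
    unmapped_reads = sum(reads$count[reads$sequence %in% unmapped]))
  gr
}
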