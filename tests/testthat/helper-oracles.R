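## Independent brute-force oracles used across the suite.  Each is a
## deliberately naive re-derivation of an operation's definition, kept
## free of the package's own code paths.

## random DNA string
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## reads data.frame shorthand
reads_df <- function(seqs, counts = NULL, sample_id = "s1") {
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  data.frame(sequence = seqs, count = as.integer(counts),
             sample_id = rep(sample_id, length.out = length(seqs)),
             stringsAsFactors = FALSE)
}

## naive all-occurrence exact mapping by substring scan on both strands;
## returns data.frame(sequence, scaffold, start, strand), start 1-based
naive_scan_map <- function(seqs, genome_chr) {
  out <- list()
  rc_all <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    if (grepl("N", s, fixed = TRUE)) next
    for (sc in names(genome_chr)) {
      g <- genome_chr[[sc]]
      for (str in c("+", "-")) {
        pat <- if (str == "+") s else rc_all[i]
        ## step-by-one rescan so overlapping occurrences are all found
        pos <- integer(0)
        from <- 1L
        while (TRUE) {
          h <- regexpr(pat, substr(g, from, nchar(g)), fixed = TRUE)
          if (h == -1L) break
          pos <- c(pos, from + h - 1L)
          from <- from + h
        }
        if (length(pos)) {
          out[[length(out) + 1L]] <- data.frame(
            sequence = s, scaffold = sc, start = pos, strand = str,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(), scaffold = character(),
                      start = integer(), strand = character()))
  }
  do.call(rbind, out)
}

## transitive-closure interval merging via graph components: two
## intervals are linked when gap <= d; merged cluster = component span.
## df: scaffold, start, end (1-based closed).  Returns merged df sorted.
closure_merge <- function(df, d) {
  out <- list()
  for (sc in sort(unique(df$scaffold))) {
    sub <- df[df$scaffold == sc, , drop = FALSE]
    ## intervals i,j linked iff start_i - end_j - 1 <= d and
    ## start_j - end_i - 1 <= d (covers overlap and gap in either order)
    adj <- (outer(sub$start, sub$end, "-") - 1L <= d) &
      (t(outer(sub$start, sub$end, "-") - 1L) <= d)
    diag(adj) <- TRUE
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
    for (k in sort(unique(comp))) {
      idx <- comp == k
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, start = min(sub$start[idx]),
        end = max(sub$end[idx]))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$start), , drop = FALSE]
}

## exhaustive substring screen: read (or its reverse complement) occurs
## as a window of any reference sequence
window_screen_hit <- function(seq, refs) {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  len <- nchar(seq)
  for (r in refs) {
    n <- nchar(r)
    if (n < len) next
    st <- seq_len(n - len + 1L)
    wins <- substring(r, st, st + len - 1L)
    if (seq %in% wins || rc %in% wins) return(TRUE)
  }
  FALSE
}

## best ungapped local identity between two sequences: for every
## diagonal, every window of length >= min_len; returns max identity
## (0 when no window reaches min_len)
best_ungapped_identity <- function(a, b, min_len = 30L) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- length(av); nb <- length(bv)
  best <- 0
  for (off in (-(nb - 1L)):(na - 1L)) {
    ia <- max(1L, 1L + off); ib <- ia - off
    len <- min(na - ia, nb - ib) + 1L
    if (len < min_len) next
    m <- av[ia:(ia + len - 1L)] == bv[ib:(ib + len - 1L)]
    cs <- c(0L, cumsum(m))
    for (w in min_len:len) {
      starts <- seq_len(len - w + 1L)
      ident <- (cs[starts + w] - cs[starts]) / w
      best <- max(best, max(ident))
    }
  }
  best
}

## GRanges construction shorthand (1-based closed)
gr <- function(scaffold, start, end, strand = "*") {
  GenomicRanges::GRanges(scaffold, IRanges::IRanges(start, end),
                         strand = strand)
}

## alignment GRanges with count metadata
aln_gr <- function(scaffold, start, end, strand = "+", count = 1L,
                   sequence = NULL, sample_id = "s1") {
  g <- gr(scaffold, start, end, strand)
  if (is.null(sequence)) sequence <- paste0("seq", seq_along(g))
  S4Vectors::mcols(g)$sequence <- sequence
  S4Vectors::mcols(g)$count <- count
  S4Vectors::mcols(g)$sample_id <- sample_id
  g
}
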