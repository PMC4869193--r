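## Positional base composition and the primary/secondary pathway ratio.
## Primary-pathway piRNAs carry uridine at position 1 (1U) from PIWI
## loading preference; secondary ("ping-pong") piRNAs carry adenine at
## position 10 (10A) from the cleavage register.  The pathway ratio
## contrasts reads that are 1U-but-not-10A against not-1U-but-10A reads;
## reads satisfying both or neither are excluded.

base_at <- function(seqs, position) substr(seqs, position, position)

#' Positional base composition of a read set
#'
#' Proportions of A/C/G/U at selected 1-based read positions, weighted by
#' collapsed read count (default, the abundance-weighted reading) or by
#' unique sequence.  Reads shorter than a position are excluded from that
#' position's denominator, as are `N` bases.  Bases are reported in RNA
#' letters (U for T).
#'
#' @param reads Collapsed read data.frame.
#' @param positions 1-based positions (default 1 and 10).
#' @param weighting `"by_read_count"` or `"by_unique_sequence"`.
#' @return data.frame with `position`, `base`, `count`, `proportion`;
#'   per-position proportions sum to 1.
#' @export
base_composition <- function(reads, positions = c(1L, 10L),
                             weighting = c("by_read_count",
                                           "by_unique_sequence")) {
  weighting <- match.arg(weighting)
  if (nrow(reads) == 0L) stop("empty read set")
  w <- if (weighting == "by_read_count") as.numeric(reads$count)
       else rep(1, nrow(reads))
  out <- lapply(positions, function(p) {
    b <- base_at(reads$sequence, p)
    ok <- b %in% c("A", "C", "G", "T")
    counts <- vapply(c("A", "C", "G", "T"),
                     function(x) sum(w[ok][b[ok] == x]), numeric(1))
    if (sum(counts) == 0)
      stop("no reads cover position ", p)
    data.frame(position = p, base = c("A", "C", "G", "U"),
               count = unname(counts),
               proportion = unname(counts) / sum(counts))
  })
  do.call(rbind, out)
}

#' Primary/secondary pathway ratio (1U/10A or 1U/10G)
#'
#' Primary reads: position 1 is U and position 10 is not X; secondary
#' reads: position 1 is not U and position 10 is X, where X is A
#' (`variant = "10A"`) or G (`variant = "10G"`).  All other reads are
#' excluded.  Ratio = primary/secondary; a zero secondary count yields
#' `Inf` and is flagged undefined.
#'
#' @param reads Collapsed read data.frame (sequences >= 10 nt).
#' @param variant `"10A"` or `"10G"`.
#' @param weighting Count reads by abundance (default) or once per unique
#'   sequence.
#' @return list with `n_primary`, `n_secondary`, `ratio`, `variant`,
#'   `undefined` (TRUE when the denominator is zero).
#' @export
pathway_ratio <- function(reads, variant = c("10A", "10G"),
                          weighting = c("by_read_count",
                                        "by_unique_sequence")) {
  variant <- match.arg(variant)
  weighting <- match.arg(weighting)
  x_base <- substr(variant, 3L, 3L)
  keep <- nchar(reads$sequence) >= 10L
  reads <- reads[keep, , drop = FALSE]
  w <- if (weighting == "by_read_count") as.numeric(reads$count)
       else rep(1, nrow(reads))
  b1 <- base_at(reads$sequence, 1L)
  b10 <- base_at(reads$sequence, 10L)
  primary <- b1 == "T" & b10 != x_base
  secondary <- b1 != "T" & b10 == x_base
  n_primary <- sum(w[primary])
  n_secondary <- sum(w[secondary])
  undefined <- n_secondary == 0
  list(n_primary = n_primary, n_secondary = n_secondary,
       ratio = if (undefined) Inf else n_primary / n_secondary,
       variant = variant, undefined = undefined)
}

#' Chi-square test for positional base bias
#'
#' Goodness of fit of the observed A/C/G/U counts at one position against
#' an expected distribution (uniform 1/4 by default; pass genome base
#' frequencies to test against genomic background), df = 3.
#'
#' @param composition data.frame from [base_composition()] (must carry
#'   counts, not just proportions).
#' @param position Position to test.
#' @param expected Expected probabilities for A/C/G/U (default uniform).
#' @return `htest` object from [stats::chisq.test()].
#' @export
bias_test <- function(composition, position, expected = rep(0.25, 4)) {
  rows <- composition[composition$position == position, ]
  if (nrow(rows) != 4L) stop("composition lacks position ", position)
  counts <- rows$count[match(c("A", "C", "G", "U"), rows$base)]
  if (sum(counts) < 20)
    warning("fewer than 20 observations: chi-square asymptotics doubtful")
  stats::chisq.test(counts, p = expected)
}
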