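test_that("length window keeps 25-32 nt inclusive", {
  r <- reads_df(vapply(c(24, 25, 32, 33), rand_dna, ""))
  set.seed(1)
  kept <- length_filter(r)
  expect_equal(nchar(kept$sequence), c(25L, 32L))
  expect_equal(nrow(length_filter(reads_df(character()))), 0L)
  all28 <- reads_df(replicate(5, rand_dna(28)))
  expect_equal(length_filter(all28), all28)
  expect_error(length_filter(r, 30, 20), "min_len")
})

test_that("sequence-set screen removes hairpin windows on either strand", {
  set.seed(21)
  hairpin <- rand_dna(70)
  win <- substr(hairpin, 11, 38)                   # 28-nt window
  rc_win <- revcomp(substr(hairpin, 20, 47))
  ## mutate one position of a window -> must be kept
  near <- win
  substr(near, 14, 14) <- setdiff(c("A", "C", "G", "T"),
                                  substr(near, 14, 14))[1]
  r <- reads_df(c(win, rc_win, near, rand_dna(28)))
  kept <- exclude_by_sequence_set(r, hairpin)
  expect_false(win %in% kept$sequence)
  expect_false(rc_win %in% kept$sequence)
  expect_true(near %in% kept$sequence)
})

test_that("sequence-set screen agrees with exhaustive window oracle", {
  set.seed(22)
  refs <- replicate(8, rand_dna(sample(60:90, 1)))
  mk_read <- function() {
    kind <- sample(3, 1)
    if (kind == 1) {                       # planted window
      ref <- sample(refs, 1)
      st <- sample(nchar(ref) - 27, 1)
      substr(ref, st, st + 27)
    } else if (kind == 2) {                # mutated window
      ref <- sample(refs, 1)
      st <- sample(nchar(ref) - 27, 1)
      s <- substr(ref, st, st + 27)
      p <- sample(28, 1)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
      s
    } else rand_dna(28)
  }
  seqs <- unique(replicate(120, mk_read()))
  r <- reads_df(seqs)
  kept <- exclude_by_sequence_set(r, refs)
  oracle_hit <- vapply(seqs, window_screen_hit, TRUE, refs = refs)
  expect_setequal(kept$sequence, seqs[!oracle_hit])
})

test_that("Hamming-tolerant screen removes 1-mismatch windows", {
  set.seed(23)
  ref <- rand_dna(80)
  s <- substr(ref, 5, 32)
  substr(s, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(s, 10, 10))[1]
  r <- reads_df(c(s, rand_dna(28)))
  expect_true(s %in% exclude_by_sequence_set(r, ref)$sequence)
  expect_false(s %in%
    exclude_by_sequence_set(r, ref, max_mismatch = 1L)$sequence)
})

test_that("empty reference set warns and passes all reads", {
  r <- reads_df(rand_dna(28))
  expect_warning(out <- exclude_by_sequence_set(r, character()), "empty")
  expect_equal(out, r)
})

test_that("repeat-mask exclusion removes listed classes, keeps TEs", {
  mask <- gr("s1", c(1000, 5000, 9000), c(1200, 5300, 9100), "+")
  S4Vectors::mcols(mask)$repeat_class <-
    c("Simple_repeat", "LTR", "tRNA")
  aln <- aln_gr("s1", c(1050, 5100, 9050, 2000, 1200, 1201),
                c(1077, 5127, 9077, 2027, 1227, 1228))
  kept <- exclude_by_repeat_mask(aln, mask)
  st <- GenomicRanges::start(kept)
  expect_false(1050 %in% st)   # inside Simple_repeat
  expect_true(5100 %in% st)    # inside LTR: retained
  expect_false(9050 %in% st)   # inside tRNA
  expect_true(2000 %in% st)    # unmasked
  expect_false(1200 %in% st)   # 1 bp overlap removes
  expect_true(1201 %in% st)    # adjacent, no overlap
})

test_that("unknown repeat classes are retained with a warning", {
  mask <- gr("s1", 100, 200, "+")
  S4Vectors::mcols(mask)$repeat_class <- "MysteryClass"
  aln <- aln_gr("s1", 150, 177)
  expect_warning(kept <- exclude_by_repeat_mask(aln, mask), "Mystery")
  expect_length(kept, 1L)
})

test_that("RepeatMasker .out parsing extracts intervals and classes", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end (left)     repeat class/family  begin end (left) ID",
    "",
    "  463   1.3  0.6  1.7  s1        1001  1200 (8000) +  (TA)n    Simple_repeat    1  200   (0)  1",
    "  239  29.4  1.9  1.0  s2         501   800 (1200) C  Gypsy-1  LTR/Gypsy        1  300   (0)  2"),
    f)
  rm <- read_repeatmasker_out(f)
  expect_length(rm, 2L)
  expect_equal(S4Vectors::mcols(rm)$repeat_class, c("Simple_repeat", "LTR"))
  expect_equal(GenomicRanges::start(rm), c(1001L, 501L))
  expect_equal(as.character(GenomicRanges::strand(rm)), c("+", "-"))
})

test_that("low-abundance floor is inclusive at min_count", {
  r <- reads_df(replicate(3, rand_dna(28)), counts = c(9L, 10L, 11L))
  kept <- low_abundance_filter(r)
  expect_setequal(kept$count, c(10L, 11L))
  ones <- reads_df(replicate(4, rand_dna(28)))
  expect_equal(low_abundance_filter(ones, 1L), ones)
  expect_error(low_abundance_filter(r, 0L), "min_count")
})

test_that("removed fraction matches a mixture calibrated to 28% below 10", {
  set.seed(24)
  n <- 5000
  low <- stats::rbinom(n, 1, 0.28) == 1
  counts <- ifelse(low, sample(1:9, n, replace = TRUE),
                   sample(10:500, n, replace = TRUE))
  seqs <- vapply(seq_len(n), function(i) rand_dna(28), "")
  r <- reads_df(seqs, counts = counts)
  r <- r[!duplicated(r$sequence), ]
  removed <- 1 - nrow(low_abundance_filter(r)) / nrow(r)
  expect_equal(removed, mean(r$count < 10))
  expect_lt(abs(removed - 0.28), 0.03)
})

test_that("prefilter cascade conserves totals and filters are idempotent", {
  set.seed(25)
  mirna <- replicate(5, rand_dna(70))
  contam <- vapply(1:10, function(i) {
    st <- sample(70 - 27, 1); substr(sample(mirna, 1), st, st + 27)
  }, "")
  seqs <- c(replicate(40, rand_dna(sample(20:36, 1))), contam)
  r <- reads_df(seqs, counts = sample(1:50, length(seqs), replace = TRUE))
  r <- r[!duplicated(r$sequence), ]
  out <- prefilter_reads(r, mirna = mirna, min_count = 10)
  rep <- out$report
  input <- rep$reads_total[rep$stage == "input"]
  output <- rep$reads_total[rep$stage == "output"]
  expect_equal(sum(rep$reads_removed, na.rm = TRUE), input - output)
  expect_equal(sum(rep$unique_removed, na.rm = TRUE),
               rep$unique_total[rep$stage == "input"] -
                 rep$unique_total[rep$stage == "output"])
  ## idempotence
  expect_equal(length_filter(length_filter(r)), length_filter(r))
  expect_equal(low_abundance_filter(low_abundance_filter(r)),
               low_abundance_filter(r))
  once <- exclude_by_sequence_set(r, mirna)
  expect_equal(exclude_by_sequence_set(once, mirna), once)
})
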