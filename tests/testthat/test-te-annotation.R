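test_that("TE library headers parse id and class", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">Tx1#LINE", "ACGTACGT", ">helix", "GGGGCCCC"), f)
  lib <- read_te_library(f)
  expect_equal(lib$te_id, c("Tx1", "helix"))
  expect_equal(lib$class, c("LINE", "unknown"))
})

test_that("planted exact and diverged TE copies are matched correctly", {
  set.seed(71)
  te <- data.frame(te_id = "TE1", class = "LINE", sequence = rand_dna(200))
  exact_cluster <- paste0(rand_dna(150), te$sequence, rand_dna(150))
  heavy <- strsplit(te$sequence, "")[[1]]
  mut <- sample(200, 30)                     # 15% divergence
  for (i in mut) heavy[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                            heavy[i]), 1)
  heavy_cluster <- paste0(rand_dna(150), paste(heavy, collapse = ""),
                          rand_dna(150))
  seqs <- c(cl_exact = exact_cluster, cl_heavy = heavy_cluster,
            cl_none = rand_dna(400))
  hits <- match_clusters_to_tes(seqs, te, min_identity = 0.90)
  expect_true("cl_exact" %in% hits$cluster_id)
  expect_equal(hits$identity[hits$cluster_id == "cl_exact"], 1.0)
  ## every reported hit must be confirmed by the exhaustive
  ## ungapped-identity oracle at the same threshold
  for (cid in unique(hits$cluster_id)) {
    expect_gte(best_ungapped_identity(seqs[[cid]], te$sequence), 0.90)
  }
  ## the oracle confirms the exact copy reaches identity 1
  expect_equal(best_ungapped_identity(exact_cluster, te$sequence), 1.0)
})

test_that("reverse-orientation TE copies are found", {
  set.seed(72)
  te <- data.frame(te_id = "TE1", class = "DNA", sequence = rand_dna(180))
  cl <- paste0(rand_dna(100), revcomp(te$sequence), rand_dna(100))
  hits <- match_clusters_to_tes(c(c1 = cl), te)
  expect_equal(hits$cluster_id, "c1")
  expect_equal(hits$identity, 1.0)
})

test_that("identity threshold is monotone", {
  set.seed(73)
  lib <- data.frame(te_id = paste0("TE", 1:4),
                    class = c("DNA", "LINE", "LTR", "SINE"),
                    sequence = replicate(4, rand_dna(200)))
  mk_copy <- function(seq, rate) {
    ch <- strsplit(seq, "")[[1]]
    mut <- sample(length(ch), round(rate * length(ch)))
    for (i in mut) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  seqs <- vapply(1:4, function(i)
    paste0(rand_dna(80), mk_copy(lib$sequence[i], c(0, 0.02, 0.06, 0.2)[i]),
           rand_dna(80)), "")
  names(seqs) <- paste0("c", 1:4)
  h90 <- match_clusters_to_tes(seqs, lib, min_identity = 0.90)
  h95 <- match_clusters_to_tes(seqs, lib, min_identity = 0.95)
  key <- function(h) paste(h$cluster_id, h$te_id)
  expect_true(all(key(h95) %in% key(h90)))
  expect_true(all(h90$identity >= 0.90))
  expect_true(all(h95$identity >= 0.95))
})

test_that("external tabular hits are parsed and thresholded", {
  f <- withr::local_tempfile(fileext = ".tab")
  writeLines(c(
    paste(c("c1", "TE1", "98.5", "200", "3", "0", "1", "200", "1", "200",
            "1e-50", "350"), collapse = "\t"),
    paste(c("c2", "TE2", "85.0", "150", "22", "1", "1", "150", "1", "150",
            "1e-20", "120"), collapse = "\t")), f)
  lib <- data.frame(te_id = c("TE1", "TE2"), class = c("LINE", "DNA"),
                    sequence = c("A", "C"))
  hits <- match_clusters_to_tes(NULL, lib, engine = "external", hits = f)
  expect_equal(hits$cluster_id, "c1")      # 85% hit fails the threshold
  expect_equal(hits$class, "LINE")
  bad <- withr::local_tempfile()
  writeLines("c1\tTE1\tonly-three", bad)
  expect_error(read_blast_tabular(bad), "malformed")
})

test_that("class enrichment equals the pooled two-proportion formula", {
  ## 30 of 100 distinct hit TEs are LINE vs 10 of 100 in the library
  libc <- data.frame(te_id = paste0("L", 1:100),
                     class = rep(c("LINE", "DNA"), c(10, 90)),
                     sequence = "A")
  hitsc <- data.frame(cluster_id = paste0("c", 1:100),
                      te_id = paste0("L", 1:100),
                      class = rep(c("LINE", "DNA"), c(30, 70)),
                      identity = 0.95, length = 100, score = 95)
  enr <- te_class_enrichment(hitsc, libc)
  line <- enr[enr$class == "LINE", ]
  expect_equal(line$proportion_hit, 0.30)
  expect_equal(line$proportion_library, 0.10)
  p_hat <- (30 + 10) / 200
  z <- (abs(0.30 - 0.10) - (1 / 100 + 1 / 100) / 2) /
    sqrt(p_hat * (1 - p_hat) * (1 / 100 + 1 / 100))
  expect_equal(line$p_value, 2 * stats::pnorm(-z), tolerance = 1e-10)
  expect_equal(line$flag, "***")
  ## identical proportions: p near 1, no flag
  hits_same <- hitsc
  hits_same$class <- rep(c("LINE", "DNA"), c(10, 90))
  enr2 <- te_class_enrichment(hits_same, libc)
  expect_gt(enr2$p_value[enr2$class == "LINE"], 0.9)
  expect_equal(enr2$flag[enr2$class == "LINE"], "")
  ## per-set class proportions sum to one
  expect_equal(sum(enr$proportion_hit), 1)
  expect_equal(sum(enr$proportion_library), 1)
})

test_that("hit classes absent from the library are skipped with warning", {
  lib <- data.frame(te_id = "T1", class = "DNA", sequence = "A")
  hits <- data.frame(cluster_id = c("c1", "c2"), te_id = c("T1", "Z9"),
                     class = c("DNA", "Mystery"), identity = 0.95,
                     length = 100, score = 95)
  expect_warning(enr <- te_class_enrichment(hits, lib), "skipped")
  expect_false("Mystery" %in% enr$class)
})

test_that("chi-square enrichment p agrees with a permutation test", {
  set.seed(74)
  lib <- data.frame(te_id = paste0("T", 1:150),
                    class = sample(c("LINE", "DNA", "LTR"), 150, TRUE,
                                   prob = c(0.3, 0.4, 0.3)),
                    sequence = "A")
  hit_idx <- sample(150, 60)
  hits <- data.frame(cluster_id = paste0("c", seq_along(hit_idx)),
                     te_id = lib$te_id[hit_idx],
                     class = lib$class[hit_idx],
                     identity = 0.95, length = 100, score = 95)
  enr <- te_class_enrichment(hits, lib)
  ## two-sample label permutation: pool the class labels of the two
  ## compared sets, reshuffle, and redraw groups of the same sizes
  pooled <- c(hits$class, lib$class)
  n_hit <- nrow(hits)
  for (cl in enr$class) {
    d_obs <- abs(enr$proportion_hit[enr$class == cl] -
                   enr$proportion_library[enr$class == cl])
    d_perm <- replicate(2000, {
      lab <- sample(pooled)
      abs(mean(lab[seq_len(n_hit)] == cl) - mean(lab[-seq_len(n_hit)] == cl))
    })
    p_perm <- mean(d_perm >= d_obs - 1e-12)
    expect_lt(abs(enr$p_value[enr$class == cl] - p_perm), 0.1)
  }
})

test_that("fraction of clusters with hits counts distinct clusters", {
  clusters <- as_cluster_set(gr("s1", c(1, 3001, 6001) * 2,
                                c(1, 3001, 6001) * 2 + 500), "final")
  hits <- data.frame(cluster_id = c(names(clusters)[1], names(clusters)[1],
                                    names(clusters)[2]),
                     te_id = c("T1", "T2", "T1"), class = "DNA",
                     identity = 1, length = 100, score = 100)
  expect_equal(fraction_clusters_with_hit(hits, clusters), 2 / 3)
  expect_equal(fraction_clusters_with_hit(hits[0, ], clusters), 0)
})

test_that("miRNA QC detects hairpins embedded in the reference", {
  set.seed(75)
  hp <- rand_dna(70)
  clean <- c(c1 = rand_dna(300))
  dirty <- c(c1 = paste0(rand_dna(100), hp, rand_dna(100)))
  expect_true(reference_mirna_qc(clean, hp)$clean)
  qc <- reference_mirna_qc(dirty, hp)
  expect_false(qc$clean)
  expect_equal(qc$n_hairpins_found, 1L)
})
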