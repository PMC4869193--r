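test_that("size factors follow the median-of-ratios definition", {
  set.seed(81)
  base <- rnbinom(200, mu = 100, size = 5) + 1
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- paste0("c", 1:200)
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(s1 = base, s2 = 2 * base)
  rownames(m2) <- rownames(m)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(prod(sf), 1)               # rescaled to geometric mean 1
  expect_error(size_factors(matrix(0, 3, 2,
                                   dimnames = list(letters[1:3],
                                                   c("a", "b")))),
               "all-zero")
})

test_that("a planted 3x library-size column is recovered", {
  set.seed(82)
  mu <- rlnorm(500, log(100), 1)
  m <- sapply(c(1, 1, 3, 1), function(f)
    rnbinom(500, mu = f * mu, size = 10))
  dimnames(m) <- list(paste0("c", 1:500), paste0("s", 1:4))
  sf <- size_factors(m)
  expect_lt(abs(sf[["s3"]] / sf[["s1"]] - 3), 0.3)
})

test_that("fold change and p-value behave on canonical inputs", {
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  set.seed(83)
  stable <- rnbinom(50, mu = 100, size = 10) + 10
  m <- cbind(a1 = stable, a2 = stable, b1 = stable, b2 = stable)
  rownames(m) <- paste0("c", 1:50)
  de <- differential_expression(m, "A", "B", groups = groups)
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$p_value == 1))
  expect_false(any(de$passes_de_filter))
  ## planted zero-vs-100 cluster: log2fc = log2(100.5/0.5)
  m2 <- rbind(m, target = c(0, 0, 100, 100))
  de2 <- differential_expression(m2, "A", "B", groups = groups)
  tgt <- de2[de2$cluster_id == "target", ]
  expect_equal(tgt$log2fc, log2(100.5 / 0.5), tolerance = 0.05)
  expect_true(tgt$passes_de_filter)
  ## swapping groups negates log2fc and keeps p
  de3 <- differential_expression(m2, "B", "A", groups = groups)
  expect_equal(de3$log2fc, -de2$log2fc, tolerance = 1e-8)
  expect_equal(de3$p_value, de2$p_value, tolerance = 1e-8)
  expect_error(differential_expression(m2, "A", "Z", groups = groups),
               "no samples")
})

test_that("external p-values override the built-in test", {
  groups <- c(a1 = "A", b1 = "B", a2 = "A", b2 = "B")
  set.seed(84)
  m <- matrix(rnbinom(200, mu = 50, size = 5), 50,
              dimnames = list(paste0("c", 1:50),
                              c("a1", "b1", "a2", "b2")))
  pext <- stats::setNames(rep(0.42, 50), paste0("c", 1:50))
  de <- differential_expression(m, "A", "B", groups = groups,
                                p_external = pext)
  expect_true(all(de$p_value == 0.42))
})

test_that("null simulations keep the type-I error near nominal", {
  set.seed(85)
  n <- 800
  m <- matrix(rnbinom(n * 6, mu = 200, size = 1 / 0.2), n,
              dimnames = list(paste0("c", 1:n), paste0("s", 1:6)))
  groups <- stats::setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  de <- differential_expression(m, "A", "B", groups = groups)
  expect_lte(mean(de$p_value < 0.05), 0.075)
  expect_gte(mean(de$p_value < 0.05), 0.01)   # not absurdly conservative
})

test_that("planted 8-fold changes are detected with good power", {
  set.seed(86)
  n_null <- 400; n_de <- 100
  mu_a <- rep(200, n_null + n_de)
  mu_b <- c(rep(200, n_null), rep(1600, n_de))
  m <- cbind(sapply(1:3, function(i) rnbinom(length(mu_a), mu = mu_a,
                                             size = 5)),
             sapply(1:3, function(i) rnbinom(length(mu_b), mu = mu_b,
                                             size = 5)))
  dimnames(m) <- list(paste0("c", seq_along(mu_a)), paste0("s", 1:6))
  groups <- stats::setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  de <- differential_expression(m, "A", "B", groups = groups)
  expect_gte(mean(de$passes_de_filter[-(1:n_null)]), 0.8)
  expect_lte(mean(de$passes_de_filter[1:n_null]), 0.02)
})

test_that("expression and DE filters implement the printed thresholds", {
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  stable <- rep(100, 20)
  m <- rbind(matrix(stable, 5, 4), big = c(8, 8, 200, 200))
  colnames(m) <- names(groups)
  rownames(m) <- c(paste0("c", 1:5), "big")
  de <- differential_expression(m, "A", "B", groups = groups)
  big <- de[de$cluster_id == "big", ]
  expect_true(big$passes_expression_filter)   # max group mean 200 > 10
  small <- rbind(matrix(stable, 5, 4), tiny = c(0, 0, 6, 6))
  colnames(small) <- names(groups)
  rownames(small) <- c(paste0("c", 1:5), "tiny")
  de2 <- differential_expression(small, "A", "B", groups = groups)
  tiny <- de2[de2$cluster_id == "tiny", ]
  expect_false(tiny$passes_expression_filter) # both means <= 10
})

test_that("accounting reports directional counts and 1-decimal percents", {
  res <- data.frame(cluster_id = paste0("c", 1:8),
                    log2fc = c(-3, -2.5, 2.2, 3, 0, -3, 2.5, 1),
                    p_value = c(0.01, 0.2, 0.01, 0.03, 0.5, 0.04, 0.2, 0.01),
                    passes_de_filter = c(TRUE, FALSE, TRUE, TRUE, FALSE,
                                         TRUE, FALSE, FALSE))
  acc <- de_accounting(res)
  expect_equal(acc$n_down, 2)
  expect_equal(acc$n_up, 2)
  expect_equal(acc$n_tested, 8)
  expect_equal(acc$pct_down, 25)
  none <- de_accounting(transform(res, passes_de_filter = FALSE))
  expect_equal(c(none$n_down, none$n_up, none$pct_down, none$pct_up),
               c(0, 0, 0, 0))
})

test_that("direction calls agree with DESeq2 on a planted matrix", {
  skip_if_not_installed("DESeq2")
  set.seed(87)
  n <- 60
  mu_b <- c(rep(100, 40), rep(800, 10), rep(12, 10))
  m <- cbind(sapply(1:3, function(i) rnbinom(n, mu = 100, size = 5)),
             sapply(1:3, function(i) rnbinom(n, mu = mu_b, size = 5)))
  dimnames(m) <- list(paste0("c", 1:n), paste0("s", 1:6))
  groups <- stats::setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  de <- differential_expression(m, "A", "B", groups = groups)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      m, data.frame(condition = factor(rep(c("A", "B"), each = 3))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    rr <- as.data.frame(DESeq2::results(dds))
  })
  strong <- which(!is.na(rr$padj) & rr$padj < 0.01 & abs(rr$log2FoldChange) > 1)
  expect_gt(length(strong), 10)
  expect_true(all(sign(de$log2fc[strong]) == sign(rr$log2FoldChange[strong])))
  expect_gt(stats::cor(de$log2fc, rr$log2FoldChange), 0.95)
})
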