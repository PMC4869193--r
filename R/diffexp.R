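## Lightweight differential expression for cluster count matrices:
## median-of-ratios normalization, method-of-moments dispersion shrunk
## toward a 1/mean trend, and a two-sided exact negative-binomial test on
## per-group count sums (Poisson fallback when variance <= mean).  This
## is a self-contained substitute for a full shrinkage-GLM stack,
## adequate for the fold-change/p-value screens applied downstream;
## externally computed p-values can be substituted via the `p_external`
## argument.

#' Median-of-ratios size factors
#'
#' `factor_j = median_i(count_ij / geometric_mean_i)` over clusters with
#' non-zero geometric mean, rescaled to geometric mean 1 so identical
#' columns get factor 1.
#'
#' @param counts Cluster x sample count matrix (or `pirna_counts`).
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "pirna_counts")) counts <- counts$counts
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  if (all(counts == 0)) stop("all-zero count matrix")
  loggm <- rowMeans(log(counts))
  sf <- apply(counts, 2L, function(col) {
    r <- (log(col) - loggm)[is.finite(loggm) & col > 0]
    if (!length(r)) stop("a sample shares no expressed cluster with ",
                         "the geometric mean; cannot normalize")
    exp(stats::median(r))
  })
  sf / exp(mean(log(sf)))
}

## per-cluster method-of-moments dispersion, shrunk toward an
## a0 + a1/mean trend fitted across clusters
estimate_dispersions <- function(counts, sf, groups, prior_df = 10) {
  q <- sweep(counts, 2L, sf, "/")
  grp <- split(seq_along(sf), groups)
  mu <- rowMeans(q)
  ## pooled within-group variance of normalized counts
  ss <- 0
  df <- 0
  for (idx in grp) {
    if (length(idx) < 2L) next
    gq <- q[, idx, drop = FALSE]
    ss <- ss + rowSums((gq - rowMeans(gq))^2)
    df <- df + length(idx) - 1L
  }
  if (df == 0L) {
    ## no replication: fall back to Poisson
    return(rep(0, nrow(counts)))
  }
  v <- ss / df
  xi <- mean(1 / sf)
  alpha_mom <- (v - xi * mu) / mu^2
  alpha_mom[!is.finite(alpha_mom)] <- NA
  fit_ok <- !is.na(alpha_mom) & alpha_mom > 0 & mu > 0
  if (sum(fit_ok) >= 10L) {
    co <- stats::coef(stats::lm(alpha_mom[fit_ok] ~ I(1 / mu[fit_ok])))
    co[is.na(co) | co < 0] <- 0
    alpha_tr <- co[1L] + co[2L] / pmax(mu, 1e-8)
  } else {
    alpha_tr <- rep(mean(alpha_mom[fit_ok], na.rm = TRUE), nrow(counts))
    alpha_tr[is.na(alpha_tr)] <- 0
  }
  am <- pmax(ifelse(is.na(alpha_mom), 0, alpha_mom), 0)
  alpha <- (df * am + prior_df * alpha_tr) / (df + prior_df)
  pmax(alpha, 0)
}

## two-sided exact NB test on group count sums, conditioning on the total
nb_exact_p <- function(kA, kB, sA, sB, sA2, sB2, alpha) {
  kS <- kA + kB
  if (kS == 0) return(1)
  q0 <- kS / (sA + sB)
  muA <- q0 * sA
  muB <- q0 * sB
  vA <- muA + alpha * q0^2 * sA2
  vB <- muB + alpha * q0^2 * sB2
  a <- 0:kS
  dens <- function(x, mu, v) {
    if (v > mu * (1 + 1e-8)) {
      stats::dnbinom(x, mu = mu, size = mu^2 / (v - mu))
    } else {
      stats::dpois(x, mu)
    }
  }
  p_all <- dens(a, muA, vA) * dens(kS - a, muB, vB)
  tot <- sum(p_all)
  if (tot == 0) return(1)
  p_obs <- p_all[kA + 1L]
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-7)]) / tot)
}

#' Differential expression between two groups of samples
#'
#' Computes per-cluster normalized group means, `log2fc =
#' log2((mean_B + pseudocount) / (mean_A + pseudocount))`, and a
#' two-sided exact negative-binomial p-value on the group count sums.
#' Two screens are reported: the expression filter (at least one group
#' with mean raw count > 10 and `|log2fc| > 2`) and the DE filter (fold
#' change > 4, i.e. `|log2fc| > 2`, with `p < 0.05`).
#'
#' @param cm `pirna_counts` object, or a plain count matrix.
#' @param group_a,group_b Group labels (baseline A, contrast B; log2fc is
#'   B over A).
#' @param groups Named vector mapping sample id to group label; defaults
#'   to the sample roles in `cm`.
#' @param pseudocount Added to both normalized means for a finite log2fc
#'   on zero counts (default 0.5).
#' @param p_external Optional named vector of per-cluster p-values from
#'   an external engine, substituted for the built-in test.
#' @param expressed_min,lfc_min,p_max Filter thresholds (defaults 10, 2,
#'   0.05).
#' @return data.frame with one row per cluster: `cluster_id`,
#'   `mean_norm_a`, `mean_norm_b`, `log2fc`, `p_value`,
#'   `passes_expression_filter`, `passes_de_filter`.
#' @export
differential_expression <- function(cm, group_a, group_b, groups = NULL,
                                    pseudocount = 0.5, p_external = NULL,
                                    expressed_min = 10, lfc_min = 2,
                                    p_max = 0.05) {
  counts <- if (inherits(cm, "pirna_counts")) cm$counts else as.matrix(cm)
  if (is.null(groups)) {
    if (!inherits(cm, "pirna_counts"))
      stop("groups must be given for a plain matrix")
    groups <- cm$roles
  }
  groups <- groups[colnames(counts)]
  idxA <- which(groups == group_a)
  idxB <- which(groups == group_b)
  if (!length(idxA)) stop("no samples in group ", group_a)
  if (!length(idxB)) stop("no samples in group ", group_b)
  sub <- counts[, c(idxA, idxB), drop = FALSE]
  sf <- size_factors(sub)
  gl <- rep(c("A", "B"), c(length(idxA), length(idxB)))
  alpha <- estimate_dispersions(sub, sf, gl)
  q <- sweep(sub, 2L, sf, "/")
  meanA <- rowMeans(q[, gl == "A", drop = FALSE])
  meanB <- rowMeans(q[, gl == "B", drop = FALSE])
  log2fc <- log2((meanB + pseudocount) / (meanA + pseudocount))
  sA <- sum(sf[gl == "A"]); sB <- sum(sf[gl == "B"])
  sA2 <- sum(sf[gl == "A"]^2); sB2 <- sum(sf[gl == "B"]^2)
  kA <- rowSums(sub[, gl == "A", drop = FALSE])
  kB <- rowSums(sub[, gl == "B", drop = FALSE])
  pv <- vapply(seq_len(nrow(sub)), function(i) {
    nb_exact_p(kA[i], kB[i], sA, sB, sA2, sB2, alpha[i])
  }, numeric(1))
  ids <- rownames(sub)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(sub)))
  if (!is.null(p_external)) {
    sub_p <- p_external[ids]
    pv <- ifelse(is.na(sub_p), pv, sub_p)
  }
  rawA <- rowMeans(sub[, gl == "A", drop = FALSE])
  rawB <- rowMeans(sub[, gl == "B", drop = FALSE])
  data.frame(
    cluster_id = ids,
    mean_norm_a = meanA, mean_norm_b = meanB,
    log2fc = log2fc, p_value = pv,
    passes_expression_filter = pmax(rawA, rawB) > expressed_min &
      abs(log2fc) > lfc_min,
    passes_de_filter = abs(log2fc) > lfc_min & pv < p_max,
    stringsAsFactors = FALSE)
}

#' Percentages of up/down regulated clusters
#'
#' `pct = 100 * n / n_tested`, reported to one decimal.
#'
#' @param n_down,n_up Cluster counts per direction.
#' @param n_tested Total clusters tested.
#' @return list with `n_down`, `n_up`, `pct_down`, `pct_up`, `n_tested`.
#' @export
de_percentages <- function(n_down, n_up, n_tested) {
  list(n_down = n_down, n_up = n_up,
       pct_down = round(100 * n_down / n_tested, 1L),
       pct_up = round(100 * n_up / n_tested, 1L),
       n_tested = n_tested)
}

#' Summarise a differential-expression result table
#'
#' Counts clusters passing the DE filter per direction (down: `log2fc <
#' 0`, up: `log2fc > 0`) with percentages of all tested clusters.
#'
#' @param results data.frame from [differential_expression()].
#' @return list as in [de_percentages()].
#' @export
de_accounting <- function(results) {
  de <- results$passes_de_filter
  de_percentages(n_down = sum(de & results$log2fc < 0),
                 n_up = sum(de & results$log2fc > 0),
                 n_tested = nrow(results))
}
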