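#' Extract a network's feature matrix from a cohort
#'
#' Pulls one property (participation coefficient or within-module degree) of
#' every node in one network, as a subjects x nodes matrix aligned with the
#' cohort's subject order.
#'
#' @param cohort An `"sst_cohort"` (see [generate_cohort()] or
#'   [as_cohort()]).
#' @param network Network label present in the cohort's parcellation.
#' @param property `"pc"` or `"wmd"`.
#' @return Numeric matrix, rownames = subject ids, colnames = node ids.
#' @export
build_feature_block <- function(cohort, network, property = c("pc", "wmd")) {
  property <- match.arg(property)
  stopifnot_param(inherits(cohort, "sst_cohort"), "cohort must be an sst_cohort")
  stopifnot_param(network %in% unique(cohort$metrics$network),
                  sprintf("unknown network '%s'", network))
  d <- cohort$metrics[cohort$metrics$network == network,
                      c("subject", "node_id", property)]
  wide <- tidyr::pivot_wider(d, names_from = "node_id",
                             values_from = dplyr::all_of(property))
  wide <- wide[match(cohort$behavior$subject, wide$subject), , drop = FALSE]
  X <- as.matrix(wide[, -1, drop = FALSE])
  rownames(X) <- wide$subject
  X
}

# QR of the intercept-augmented design, with an explicit rank check:
# rank deficiency is an error, never silently regularized.
design_qr <- function(X) {
  X <- as.matrix(X)
  D <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    abort(sprintf("rank-deficient design: rank %d < %d columns",
                  qrd$rank, ncol(D)),
          class = "stopnet_rank_error")
  }
  qrd
}

#' Leave-one-out cross-validated OLS predictions
#'
#' For each subject `i`, an ordinary-least-squares model with intercept is
#' fitted on the remaining `n - 1` subjects and used to predict subject `i`.
#' Computed exactly through the hat-matrix leave-one-out identity
#' `yhat(-i) = (yhat_i - h_i y_i) / (1 - h_i)`; a training fold that would be
#' rank-deficient (leverage 1) is an error naming the fold.
#'
#' @param X n x k predictor matrix (no intercept column); k may be 0.
#' @param y Length-n response.
#' @return Length-n vector of out-of-fold predictions.
#' @export
loocv_predict <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot_param(nrow(X) == n, "X and y sizes differ")
  stopifnot_param(n >= ncol(X) + 3, "need n >= k + 3 subjects")
  qrd <- design_qr(X)
  Q <- qr.Q(qrd)
  h <- rowSums(Q^2)
  bad <- which(h >= 1 - 1e-10)
  if (length(bad)) {
    abort(sprintf("training fold without subject %d is rank-deficient", bad[1]),
          class = "stopnet_rank_error")
  }
  fitted <- Q %*% crossprod(Q, y)
  as.numeric((fitted - h * y) / (1 - h))
}

#' Partial Pearson correlation controlling a covariate
#'
#' Pearson correlation of the residuals of `a` and `b` after each has been
#' regressed (with intercept) on the covariate.
#'
#' @param a,b Numeric vectors, length n >= 4.
#' @param covariate Numeric covariate of the same length.
#' @return Partial correlation coefficient.
#' @export
partial_pearson <- function(a, b, covariate) {
  n <- length(a)
  stopifnot_param(n >= 4 && length(b) == n && length(covariate) == n,
                  "a, b, covariate must have equal length >= 4")
  stopifnot_param(all(is.finite(c(a, b, covariate))), "inputs must be finite")
  Z <- cbind(1, covariate)
  qz <- qr(Z)
  ra <- qr.resid(qz, a)
  rb <- qr.resid(qz, b)
  # residual variance at round-off scale counts as zero
  if (sum(ra^2) <= 1e-20 * max(1, sum(a^2)) ||
      sum(rb^2) <= 1e-20 * max(1, sum(b^2))) {
    abort("zero-variance residuals: partial correlation undefined",
          class = "stopnet_input_error")
  }
  cor(ra, rb)
}

# Observed prediction statistic shared by the permutation test and its null:
# partial r between the LOOCV predictions (trained on yy) and yy, motion out.
loocv_partial_stat <- function(Q, h, yy, qz) {
  fitted <- Q %*% crossprod(Q, yy)
  pred <- as.numeric((fitted - h * yy) / (1 - h))
  ra <- qr.resid(qz, pred)
  rb <- qr.resid(qz, yy)
  sa <- sqrt(sum(ra^2)); sb <- sqrt(sum(rb^2))
  if (sa == 0 || sb == 0) return(NA_real_)
  sum(ra * rb) / (sa * sb)
}

#' Permutation test of LOOCV prediction accuracy
#'
#' Observed statistic: partial Pearson correlation (controlling the
#' covariate) between the leave-one-out predictions and the observed
#' response. Each permutation shuffles the response, retrains the whole
#' LOOCV on the shuffled response, and recomputes the identical statistic;
#' the covariate stays attached to subjects. The p-value uses add-one
#' smoothing, `p = (1 + #{null >= observed}) / (1 + n_iter)`.
#'
#' @inheritParams loocv_predict
#' @param covariate Nuisance covariate (e.g. head motion), length n.
#' @param n_iter Number of permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @return List with `statistic` (observed partial r), `p_value`, `n_iter`,
#'   and `null` (the permutation distribution of the statistic).
#' @export
permutation_pvalue <- function(X, y, covariate, n_iter = 10000, seed = NULL) {
  if (n_iter < 100) warn("n_iter < 100 gives an unstable permutation p-value")
  X <- as.matrix(X)
  y <- as.numeric(y)
  qrd <- design_qr(X)
  Q <- qr.Q(qrd)
  h <- rowSums(Q^2)
  if (any(h >= 1 - 1e-10)) {
    abort("a leave-one-out training fold is rank-deficient",
          class = "stopnet_rank_error")
  }
  qz <- qr(cbind(1, covariate))
  observed <- loocv_partial_stat(Q, h, y, qz)
  null <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      loocv_partial_stat(Q, h, y[sample.int(length(y))], qz)
    }, numeric(1))
  })
  # exact ties (e.g. degenerate statistics) count as >= despite float jitter
  tie_tol <- 1e-12 * max(1, abs(observed))
  p <- (1 + sum(null >= observed - tie_tol, na.rm = TRUE)) / (1 + n_iter)
  list(statistic = observed, p_value = p, n_iter = n_iter, null = null)
}

# Gauss hypergeometric 2F1(a, b; c; z) by power series; converges for z in
# [0, 1) and, when c - a - b > 0, absolutely up to z = 1.
hyp2f1 <- function(a, b, c, z, tol = 1e-12, max_iter = 20000) {
  term <- 1
  total <- 1
  for (k in seq_len(max_iter)) {
    term <- term * (a + k - 1) * (b + k - 1) / ((c + k - 1) * k) * z
    total <- total + term
    if (abs(term) < tol * abs(total)) return(total)
  }
  warn("hypergeometric series did not fully converge")
  total
}

# Exact sampling density of the Pearson correlation r given population rho,
# sample size n (normal model). Vectorized over rho.
pearson_r_density <- function(r, rho, n) {
  vapply(rho, function(p) {
    log_f <- log(n - 2) + lgamma(n - 1) +
      ((n - 1) / 2) * log1p(-p^2) +
      ((n - 4) / 2) * log1p(-r^2) -
      0.5 * log(2 * pi) - lgamma(n - 1 / 2) -
      (n - 3 / 2) * log1p(-p * r)
    if (!is.finite(log_f)) return(0)
    exp(log_f) * hyp2f1(0.5, 0.5, n - 0.5, (p * r + 1) / 2)
  }, numeric(1))
}

#' Jeffreys Bayes factor for a Pearson correlation
#'
#' Default Bayes factor comparing the alternative (a correlation is present,
#' uniform prior on rho over the admissible interval) against the nil
#' hypothesis rho = 0, computed by numerical integration of the exact
#' sampling density of `r`. `BF10 > 1` favors the presence of a correlation;
#' conventional bands read 1-3 as anecdotal and 3-10 as moderate evidence.
#'
#' @param r Observed Pearson correlation, `|r| < 1`.
#' @param n Sample size, `n >= 4`.
#' @param sided `"two"` (default; prior uniform on (-1, 1)) or `"positive"`
#'   (prior uniform on (0, 1), evidence for a positive correlation).
#' @return The Bayes factor (a positive number; `Inf` when `|r| = 1`).
#' @examples
#' bf10_correlation(0.3, 50)
#' @export
bf10_correlation <- function(r, n, sided = c("two", "positive")) {
  sided <- match.arg(sided)
  stopifnot_param(is.finite(n) && n >= 4, "need n >= 4")
  stopifnot_param(abs(r) <= 1, "|r| must be <= 1")
  if (abs(r) == 1) return(Inf)
  lower <- if (sided == "two") -1 else 0
  prior_height <- 1 / (1 - lower)
  marginal <- integrate(function(rho) pearson_r_density(r, rho, n) * prior_height,
                        lower = lower, upper = 1,
                        rel.tol = 1e-9, subdivisions = 500L)$value
  marginal / pearson_r_density(r, 0, n)
}

#' Post-hoc power of the overall F test of a multiple regression
#'
#' Observed power of the k-predictor regression F test at significance
#' `alpha`, using Cohen's effect size `f2 = R2 / (1 - R2)` and the
#' noncentral F distribution with degrees of freedom `(k, n - k - 1)`. The
#' noncentrality is `f2 * n` by default (`ncp = "n"`); `ncp = "df"` uses the
#' df-adjusted `f2 * (n - k - 1)`.
#'
#' @param R2 Coefficient of determination of the fitted model, in \[0, 1).
#' @param n Sample size.
#' @param k Number of predictors.
#' @param alpha Significance level (default 0.05).
#' @param ncp Noncentrality convention, `"n"` or `"df"`.
#' @return Power in \[alpha, 1\].
#' @export
posthoc_power <- function(R2, n, k, alpha = 0.05, ncp = c("n", "df")) {
  ncp <- match.arg(ncp)
  stopifnot_param(R2 >= 0 && R2 < 1, "R2 must lie in [0, 1)")
  stopifnot_param(n > k + 1 && k >= 1, "need n > k + 1 and k >= 1")
  stopifnot_param(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  f2 <- R2 / (1 - R2)
  lambda <- f2 * if (ncp == "n") n else (n - k - 1)
  df2 <- n - k - 1
  crit <- qf(1 - alpha, k, df2)
  pf(crit, k, df2, ncp = lambda, lower.tail = FALSE)
}
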