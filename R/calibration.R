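#' Permutation-based effective number of independent tests
#'
#' Runs a simple-regression genome scan on `n_perm` random permutations of
#' the phenotype, recording the best p-value of each scan. For each grid
#' p-value `p`, the corrected p-value is the fraction of permutation best
#' p-values at or below `p`; the Sidak relation
#' `p_corr = 1 - (1 - p)^meff` then gives a pointwise estimate
#' `meff(p) = log(1 - p_corr) / log(1 - p)`. The returned `meff` is the
#' median of the pointwise estimates over grid points with corrected
#' p-values in \[0.01, 0.5\], clamped to \[1, n_variants\].
#'
#' @param y Phenotype vector (no missing values).
#' @param geno A [geno_matrix()] (monomorphic variants are ignored).
#' @param n_perm Number of permutations (at least 100; 10,000 by default).
#' @param p_grid Uncorrected p-values at which to evaluate the Sidak
#'   relation; by default the empirical quantiles of the permutation best-p
#'   distribution at levels 0.01-0.5.
#' @param seed Integer seed for the permutations.
#' @return A `meff_result`: `meff`, `pointwise` (grid diagnostics), `cv`
#'   (coefficient of variation of the pointwise estimates), `best_p`
#'   (permutation distribution), `n_perm`, `seed`.
#' @export
permutation_meff <- function(y, geno, n_perm = 10000, p_grid = NULL,
                             seed = 1L) {
  stopifnot(inherits(geno, "geno_matrix"), n_perm >= 100)
  if (anyNA(y)) stop("y must be complete for the permutation scan")
  d <- geno$dosages
  d[is.na(d)] <- matrix(colMeans(d, na.rm = TRUE)[col(d)],
                        nrow(d), ncol(d))[is.na(d)]
  sds <- apply(d, 2, stats::sd)
  poly <- sds > 0
  if (!any(poly)) stop("no polymorphic variants")
  G <- scale(d[, poly, drop = FALSE])
  m <- ncol(G)
  n <- length(y)
  set.seed(seed)
  P <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) P[, b] <- sample(y)
  P <- scale(P)
  ## best (largest) squared correlation per permutation scan
  r <- crossprod(G, P) / (n - 1)
  r2max <- apply(r^2, 2, max)
  tmax <- sqrt(r2max * (n - 2) / (1 - r2max))
  best_p <- 2 * stats::pt(-tmax, df = n - 2)

  if (is.null(p_grid)) {
    p_grid <- unique(stats::quantile(best_p, probs = seq(0.01, 0.5,
                                                         length.out = 25),
                                     type = 1))
  }
  p_corr <- vapply(p_grid, function(p) mean(best_p <= p), numeric(1))
  ok <- p_corr >= 0.01 & p_corr <= 0.5 & p_grid > 0 & p_grid < 1
  if (!any(ok)) {
    stop("no grid point with corrected p in [0.01, 0.5]; increase n_perm")
  }
  meff_pt <- log1p(-p_corr[ok]) / log1p(-p_grid[ok])
  meff <- min(max(stats::median(meff_pt), 1), m)
  cv <- stats::sd(meff_pt) / mean(meff_pt)
  structure(list(meff = meff,
                 pointwise = data.frame(p = p_grid[ok], p_corr = p_corr[ok],
                                        meff = meff_pt),
                 cv = cv, best_p = best_p, n_variants = m,
                 n_perm = n_perm, seed = seed),
            class = "meff_result")
}

#' @export
print.meff_result <- function(x, ...) {
  cat(sprintf(
    "Effective number of tests: %.1f (of %d variants; %d permutations, pointwise CV %.2f)\n",
    x$meff, x$n_variants, x$n_perm, x$cv))
  invisible(x)
}

#' Effective number of independent traits (Galwey)
#'
#' `meff = (sum_k sqrt(max(lambda_k, 0)))^2 / sum_k max(lambda_k, 0)` over
#' the eigenvalues of the trait correlation matrix.
#'
#' @param trait_corr T x T trait correlation matrix.
#' @return list with `meff` (real) and `meff_floor` (integer floor, the
#'   value conventionally used in Bonferroni corrections).
#' @export
galwey_meff <- function(trait_corr) {
  trait_corr <- as.matrix(trait_corr)
  if (!isSymmetric(unname(trait_corr), tol = 1e-8)) {
    stop("trait correlation matrix must be symmetric")
  }
  lam <- pmax(eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values,
              0)
  meff <- sum(sqrt(lam))^2 / sum(lam)
  list(meff = meff, meff_floor = floor(meff))
}

#' Genome-wide significance threshold
#'
#' Bonferroni threshold `alpha / (meff_tests * meff_traits)` over effective
#' numbers of independent tests and traits.
#'
#' @param alpha Family-wise error target.
#' @param meff_tests Effective number of independent tests.
#' @param meff_traits Effective number of independent traits (default 1).
#' @return list with `threshold` and `neglog10` (its -log10).
#' @export
significance_threshold <- function(alpha, meff_tests, meff_traits = 1) {
  stopifnot(alpha > 0, meff_tests > 0, meff_traits > 0)
  thr <- alpha / (meff_tests * meff_traits)
  list(threshold = thr, neglog10 = -log10(thr))
}

#' Bundle a full calibration
#'
#' @param meff_tests A number or a `meff_result`.
#' @param meff_traits A number or the output of [galwey_meff()] (its floored
#'   value is used).
#' @param alpha Family-wise error target.
#' @return A `calibration_result` with the derived threshold.
#' @export
calibration_result <- function(meff_tests, meff_traits = 1, alpha = 0.05) {
  mt <- if (inherits(meff_tests, "meff_result")) meff_tests$meff else meff_tests
  mtr <- if (is.list(meff_traits)) meff_traits$meff_floor else meff_traits
  thr <- significance_threshold(alpha, mt, mtr)
  structure(list(meff_tests = mt, meff_traits = mtr, alpha = alpha,
                 threshold = thr$threshold, neglog10 = thr$neglog10),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Significance threshold %.3g (-log10 = %.2f) for alpha = %g over %.0f tests x %g traits\n",
    x$threshold, x$neglog10, x$alpha, x$meff_tests, x$meff_traits))
  invisible(x)
}
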