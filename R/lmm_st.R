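## REML profile log-likelihood for the eigen-rotated single-trait LMM.
## h2 parameterizes sigma_g^2 / (sigma_g^2 + sigma_e^2); weights are
## w_k = h2 * lambda_k + (1 - h2), total variance profiled out.
reml_profile <- function(h2, yt, Xt, lambda) {
  n <- length(yt); p <- ncol(Xt)
  w <- h2 * lambda + (1 - h2)
  if (any(w <= 0)) return(-Inf)
  sw <- 1 / sqrt(w)
  Xs <- Xt * sw
  ys <- yt * sw
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))
  r <- ys - Xs %*% beta
  rss <- sum(r^2)
  s2 <- rss / (n - p)
  -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(w)) +
            determinant(XtX, logarithm = TRUE)$modulus[1])
}

#' Fit the null (no-variant) linear mixed model by REML
#'
#' Model: `y = X b + g + e`, `g ~ N(0, sigma_g^2 K)`, `e ~ N(0, sigma_e^2 I)`.
#' The GRM eigendecomposition rotates the model so the variance is diagonal;
#' REML then reduces to a one-dimensional optimization over the heritability
#' ratio. Individuals with missing phenotype (or covariate) are dropped and
#' the kinship re-decomposed on the subset.
#'
#' @param y Numeric vector of trait deviations, aligned with `eigen$ids`.
#' @param eigen A [grm_eigen()].
#' @param covariates Optional numeric matrix of fixed-effect covariates
#'   (intercept added automatically).
#' @return A `null_fit`: `sigma_g2`, `sigma_e2`, `h2`, `loglik`,
#'   `converged`, `n`, plus the (possibly re-subset) eigen basis used.
#' @export
fit_null <- function(y, eigen, covariates = NULL) {
  stopifnot(inherits(eigen, "grm_eigen"))
  n_all <- length(eigen$values)
  if (length(y) != n_all) stop("y length != eigen dimension")
  X <- cbind(`(Intercept)` = rep(1, n_all), covariates)
  keep <- !is.na(y) & stats::complete.cases(X)
  if (sum(keep) < ncol(X) + 2) stop("too few non-missing phenotypes")
  if (!all(keep)) {
    eigen <- subset_eigen(eigen, which(keep))
    y <- y[keep]
    X <- X[keep, , drop = FALSE]
  }
  U <- eigen$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  opt <- stats::optimize(reml_profile, interval = c(0, 1 - 1e-8),
                         yt = yt, Xt = Xt, lambda = eigen$values,
                         maximum = TRUE, tol = 1e-9)
  h2 <- opt$maximum
  w <- h2 * eigen$values + (1 - h2)
  sw <- 1 / sqrt(w)
  Xs <- Xt * sw; ys <- yt * sw
  beta <- solve(crossprod(Xs), crossprod(Xs, ys))
  rss <- sum((ys - Xs %*% beta)^2)
  s2_tot <- rss / (length(ys) - ncol(Xs))
  structure(list(sigma_g2 = h2 * s2_tot, sigma_e2 = (1 - h2) * s2_tot,
                 h2 = h2, loglik = opt$objective,
                 converged = is.finite(opt$objective),
                 n = length(ys), eigen = eigen, keep = which(keep),
                 beta = drop(beta)),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf(
    "LMM null fit (REML): n = %d, sigma_g2 = %.4f, sigma_e2 = %.4f, h2 = %.3f, logLik = %.2f\n",
    x$n, x$sigma_g2, x$sigma_e2, x$h2, x$loglik))
  invisible(x)
}

#' Single-trait mixed-model genome scan
#'
#' Wald test of the per-variant additive effect with variance components
#' fixed at the null REML estimates. The model is rotated by the GRM
#' eigenvectors and whitened; the intercept and covariates are projected
#' out once, then each variant's effect is a weighted least-squares slope.
#' P-values use a t distribution with `n - n_fixed - 1` degrees of freedom.
#' Variants collinear with the covariates (including a conditioning variant
#' tested against itself) are reported missing with reason `"collinear"`.
#'
#' @param y Trait deviations aligned with `eigen$ids`.
#' @param geno A [geno_matrix()] on the same individuals.
#' @param eigen A [grm_eigen()].
#' @param null A [fit_null()] result for the same `y`/`eigen`
#'   (and same covariates).
#' @param covariates Optional fixed-effect matrix (e.g. conditioning-variant
#'   dosages).
#' @param region Optional `list(chrom =, start =, end =)` restricting the
#'   tested variants.
#' @param trait Trait label stored in the result.
#' @return A `gwas_result` data.frame: `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `af`, `beta`, `se`, `t`, `p`, `n`, `reason`.
#' @export
st_scan <- function(y, geno, eigen, null, covariates = NULL, region = NULL,
                    trait = "trait") {
  stopifnot(inherits(null, "null_fit"), inherits(geno, "geno_matrix"))
  keep <- null$keep
  eig <- null$eigen
  y <- y[keep]
  X <- cbind(rep(1, length(keep)), covariates[keep, , drop = FALSE])
  D <- geno$dosages[keep, , drop = FALSE]
  vsel <- seq_len(nrow(geno$variants))
  if (!is.null(region)) {
    vsel <- region_index(geno, region$chrom,
                         region$start %||% -Inf, region$end %||% Inf)
  }
  v <- geno$variants[vsel, , drop = FALSE]
  D <- D[, vsel, drop = FALSE]
  D[is.na(D)] <- matrix(colMeans(D, na.rm = TRUE)[col(D)],
                        nrow(D), ncol(D))[is.na(D)]

  U <- eig$vectors
  w <- null$sigma_g2 * eig$values + null$sigma_e2
  sw <- 1 / sqrt(w)
  ys <- crossprod(U, y) * sw
  Xs <- crossprod(U, X) * sw
  Gs <- crossprod(U, D) * sw

  qrX <- qr(Xs)
  yr <- stats::resid(stats::lm.fit(Xs, ys))
  Gr <- Gs - qr.fitted(qrX, Gs)
  gty <- crossprod(Gr, yr)
  gtg <- colSums(Gr^2)
  yty <- sum(yr^2)
  n <- length(ys)
  df <- n - ncol(Xs) - 1

  tot <- colSums(Gs^2)
  bad <- gtg < 1e-8 * pmax(tot, 1)
  beta <- se <- tval <- pval <- rep(NA_real_, length(gtg))
  ok <- !bad
  beta[ok] <- gty[ok] / gtg[ok]
  rss <- pmax(yty - beta[ok]^2 * gtg[ok], 0)
  s2 <- rss / df
  se[ok] <- sqrt(s2 / gtg[ok])
  tval[ok] <- beta[ok] / se[ok]
  pval[ok] <- 2 * stats::pt(-abs(tval[ok]), df = df)
  pval[ok] <- pmin(pmax(pval[ok], .Machine$double.xmin), 1)

  out <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                    ref = v$ref, alt = v$alt, af = v$af,
                    beta = beta, se = se, t = tval, p = pval,
                    n = n,
                    reason = ifelse(bad, "collinear", NA_character_),
                    stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  attr(out, "covariates") <- colnames(covariates)
  class(out) <- c("gwas_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
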