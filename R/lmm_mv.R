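## Simultaneous diagonalization of (Vg, Ve): returns Tm such that
## Tm Ve Tm' = I and Tm Vg Tm' = diag(d). Then for every individual k,
## V_k = lambda_k Vg + Ve satisfies Tm V_k Tm' = diag(lambda_k d + 1),
## so all n TxT inversions collapse to elementwise weights.
mv_transform <- function(Vg, Ve) {
  L <- t(chol(Ve))
  Mi <- forwardsolve(L, diag(nrow(Ve)))
  B0 <- Mi %*% Vg %*% t(Mi)
  e <- eigen((B0 + t(B0)) / 2, symmetric = TRUE)
  Tm <- t(e$vectors) %*% Mi
  list(Tm = Tm, d = pmax(e$values, 0))
}

floor_pd <- function(V, floor_frac = 1e-6) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  fl <- floor_frac * sum(pmax(e$values, 0))
  if (min(e$values) >= fl) return((V + t(V)) / 2)
  e$vectors %*% (pmax(e$values, fl) * t(e$vectors))
}

#' Fit the multivariate null linear mixed model by EM-REML
#'
#' Model: `Y = X B + G + E` with rows of `G` having covariance
#' `lambda_k Vg` in the GRM eigenbasis and rows of `E` covariance `Ve`.
#' Estimated by EM on the restricted likelihood; each iteration
#' simultaneously diagonalizes `(Vg, Ve)` so the per-individual algebra is
#' vectorized. `Ve` is kept positive definite by eigenvalue flooring at
#' `1e-6` of its trace.
#'
#' @param Y Numeric matrix (individuals x T traits), aligned with
#'   `eigen$ids`; T at most 10.
#' @param eigen A [grm_eigen()].
#' @param covariates Optional fixed-effect matrix (intercept added).
#' @param max_iter,tol_ll Convergence controls (restricted log-likelihood
#'   change below `tol_ll` and relative parameter change below `1e-8`).
#' @return An `mv_null_fit`: `Vg`, `Ve`, `loglik`, `converged`, `n`,
#'   `traits`, plus the eigen basis used.
#' @export
fit_null_mv <- function(Y, eigen, covariates = NULL, max_iter = 500,
                        tol_ll = 1e-6) {
  stopifnot(inherits(eigen, "grm_eigen"))
  Y <- as.matrix(Y)
  T <- ncol(Y)
  if (T > 10) stop("at most 10 traits supported in a multivariate fit")
  n_all <- length(eigen$values)
  if (nrow(Y) != n_all) stop("Y rows != eigen dimension")
  X <- cbind(rep(1, n_all), covariates)
  keep <- stats::complete.cases(Y) & stats::complete.cases(X)
  if (!all(keep)) {
    eigen <- subset_eigen(eigen, which(keep))
    Y <- Y[keep, , drop = FALSE]
    X <- X[keep, , drop = FALSE]
  }
  n <- nrow(Y); p <- ncol(X)
  lambda <- eigen$values
  U <- eigen$vectors
  Yt <- crossprod(U, Y)
  Xt <- crossprod(U, X)

  res0 <- as.matrix(stats::resid(stats::lm.fit(X, Y)))
  S <- stats::cov(res0)
  Vg <- S / 2; Ve <- floor_pd(S / 2)

  ll_old <- -Inf; converged <- FALSE; ll <- NA_real_
  for (it in seq_len(max_iter)) {
    tr <- mv_transform(Vg, Ve)
    Tm <- tr$Tm; dvec <- tr$d
    Vmat <- outer(lambda, dvec) + 1      # n x T variances, transformed scale
    W <- 1 / Vmat
    Ys <- Yt %*% t(Tm)

    ## GLS fixed effects decouple per transformed component
    Rstar <- matrix(0, n, T)
    Ablk_ld <- 0
    XtWX_list <- vector("list", T)
    for (t in seq_len(T)) {
      sw <- sqrt(W[, t])
      Xw <- Xt * sw
      yw <- Ys[, t] * sw
      XtWX <- crossprod(Xw)
      XtWX_list[[t]] <- XtWX
      bt <- solve(XtWX, crossprod(Xw, yw))
      Rstar[, t] <- Ys[, t] - Xt %*% bt
      Ablk_ld <- Ablk_ld + determinant(XtWX, logarithm = TRUE)$modulus[1]
    }
    Rw <- Rstar * W
    PY <- Rw %*% Tm                      # row k = (P y)_k'

    ldTm <- determinant(Tm, logarithm = TRUE)$modulus[1]
    yPy <- sum(Rstar * Rw)
    ll <- -0.5 * ((n - p) * T * log(2 * pi) +
                    (sum(log(Vmat)) - 2 * n * ldTm) +
                    (Ablk_ld + 2 * p * ldTm) + yPy)

    ## EM-REML updates. A^{-1} is block diagonal across transformed
    ## components; map it back through Tm for the trace-correction term.
    ## S2(c) = sum_k c_k Vki (Xk' A^{-1} Xk) Vki with c = lambda (Vg) or 1 (Ve)
    S2g <- matrix(0, T, T); S2e <- matrix(0, T, T)
    XtWX_inv <- lapply(XtWX_list, solve)
    for (a in seq_len(p)) {
      for (b in seq_len(p)) {
        ## A^{-1} block (a, b) is diagonal across transformed components
        Gm <- diag(vapply(XtWX_inv, `[`, numeric(1), a, b), T)
        xa <- Xt[, a]; xb <- Xt[, b]
        Hg <- crossprod(W * (lambda * xa), W * xb)
        He <- crossprod(W * xa, W * xb)
        S2g <- S2g + t(Tm) %*% (Hg * Gm) %*% Tm
        S2e <- S2e + t(Tm) %*% (He * Gm) %*% Tm
      }
    }
    sumVki_l <- t(Tm) %*% (diag(colSums(lambda * W), T)) %*% Tm
    sumVki_1 <- t(Tm) %*% (diag(colSums(W), T)) %*% Tm

    Vg_new <- Vg %*% crossprod(PY * sqrt(pmax(lambda, 0))) %*% Vg / n +
      Vg - Vg %*% (sumVki_l - S2g) %*% Vg / n
    Ve_new <- Ve %*% crossprod(PY) %*% Ve / n +
      Ve - Ve %*% (sumVki_1 - S2e) %*% Ve / n
    Vg_new <- floor_pd(Vg_new, 0)
    Ve_new <- floor_pd(Ve_new)

    dpar <- max(abs(Vg_new - Vg), abs(Ve_new - Ve)) /
      max(sum(diag(Vg_new + Ve_new)), 1e-12)
    Vg <- Vg_new; Ve <- Ve_new
    if (it > 1 && abs(ll - ll_old) < tol_ll && dpar < 1e-8) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  tn <- colnames(Y) %||% paste0("trait", seq_len(T))
  dimnames(Vg) <- dimnames(Ve) <- list(tn, tn)
  structure(list(Vg = Vg, Ve = Ve, loglik = ll, converged = converged,
                 n = n, traits = tn, eigen = eigen,
                 keep = which(keep), iterations = it),
            class = "mv_null_fit")
}

#' @export
print.mv_null_fit <- function(x, ...) {
  cat(sprintf(
    "Multivariate LMM null fit (EM-REML): n = %d, T = %d, logLik = %.2f, %s after %d iterations\n",
    x$n, length(x$traits), x$loglik,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Multi-trait mixed-model genome scan
#'
#' Per variant, the T-vector of trait effects is estimated by generalized
#' least squares with `(Vg, Ve)` fixed at the null estimates, and tested
#' with a Wald statistic against a chi-square with T degrees of freedom.
#' The transformed model decouples across components, so the scan is T
#' whitened single-trait scans recombined.
#'
#' @param Y Trait matrix aligned with `eigen$ids` (same traits as `null`).
#' @param geno A [geno_matrix()] on the same individuals.
#' @param eigen A [grm_eigen()].
#' @param null An [fit_null_mv()] result.
#' @param covariates Optional fixed-effect matrix.
#' @param region Optional `list(chrom =, start =, end =)`.
#' @return An `mt_gwas_result` data.frame: variant metadata, one
#'   `beta.<trait>` column per trait, `wald`, `df`, `p`, `n`, `reason`.
#' @export
mt_scan <- function(Y, geno, eigen, null, covariates = NULL, region = NULL) {
  stopifnot(inherits(null, "mv_null_fit"), inherits(geno, "geno_matrix"))
  keep <- null$keep
  eig <- null$eigen
  Y <- as.matrix(Y)[keep, , drop = FALSE]
  T <- ncol(Y)
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

  tr <- mv_transform(null$Vg, null$Ve)
  Tm <- tr$Tm
  lambda <- eig$values
  U <- eig$vectors
  W <- 1 / (outer(lambda, tr$d) + 1)
  Ys <- crossprod(U, Y) %*% t(Tm)
  Xt <- crossprod(U, X)
  Gt <- crossprod(U, D)

  n <- nrow(Ys)
  m <- ncol(Gt)
  bstar <- matrix(NA_real_, T, m)
  istar <- matrix(NA_real_, T, m)     # information (1/var) per component
  for (t in seq_len(T)) {
    sw <- sqrt(W[, t])
    Xw <- Xt * sw
    yw <- Ys[, t] * sw
    Gw <- Gt * sw
    qrX <- qr(Xw)
    yr <- stats::resid(stats::lm.fit(Xw, yw))
    Gr <- Gw - qr.fitted(qrX, Gw)
    gtg <- colSums(Gr^2)
    ok <- gtg > 1e-8 * pmax(colSums(Gw^2), 1)
    bstar[t, ok] <- crossprod(Gr, yr)[ok] / gtg[ok]
    istar[t, ok] <- gtg[ok]
  }
  bad <- colSums(is.na(bstar)) > 0
  wald <- colSums(bstar^2 * istar)
  wald[bad] <- NA_real_
  pval <- stats::pchisq(wald, df = T, lower.tail = FALSE)
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1)
  pval[bad] <- NA_real_
  betas <- t(solve(Tm, bstar))
  colnames(betas) <- paste0("beta.", null$traits)

  out <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                    ref = v$ref, alt = v$alt, af = v$af,
                    betas, wald = wald, df = T, p = pval, n = n,
                    reason = ifelse(bad, "collinear", NA_character_),
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "traits") <- null$traits
  class(out) <- c("mt_gwas_result", "data.frame")
  out
}
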