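#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = W W' / (2 sum p_k (1 - p_k))` where `W` is the dosage matrix with
#' each column centered by twice its alternate-allele frequency. Missing
#' dosages are mean-imputed (centered value 0). Monomorphic markers are
#' excluded with a warning.
#'
#' @param geno A [geno_matrix()].
#' @param marker_subset Optional variant ids or indices to use.
#' @return A `grm` object: list with `K` (n x n matrix), `n_markers`,
#'   `method`.
#' @export
compute_grm <- function(geno, marker_subset = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- geno$dosages
  if (!is.null(marker_subset)) {
    j <- if (is.character(marker_subset)) {
      match(marker_subset, geno$variants$id)
    } else marker_subset
    if (anyNA(j)) stop("unknown marker id(s) in subset")
    d <- d[, j, drop = FALSE]
  }
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic; GRM undefined")
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic marker(s) excluded from GRM")
    d <- d[, poly, drop = FALSE]
    p <- p[poly]
  }
  if (ncol(d) < 2) stop("need at least 2 polymorphic markers")
  W <- sweep(d, 2, 2 * p)
  W[is.na(W)] <- 0
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(rownames(d), rownames(d))
  avg_diag <- mean(diag(K))
  if (avg_diag < 0.8 || avg_diag > 1.5) {
    message("GRM average diagonal ", signif(avg_diag, 3),
            " outside [0.8, 1.5]; check marker set")
  }
  structure(list(K = K, n_markers = ncol(d), method = "vanraden1"),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("GRM (", x$method, "): ", nrow(x$K), " individuals, ",
      x$n_markers, " markers, mean diagonal ",
      signif(mean(diag(x$K)), 4), "\n", sep = "")
  invisible(x)
}

#' Eigendecomposition of a GRM
#'
#' The mixed model is fitted in the rotated basis `U' y`, where the
#' polygenic covariance is diagonal. Eigenvalues below `-1e-8 * max` raise
#' an error; small negatives from numerical noise are floored at zero.
#'
#' @param grm A `grm` or a plain symmetric matrix.
#' @return A `grm_eigen` object: `values` (descending), `vectors`.
#' @export
grm_eigen <- function(grm) {
  K <- if (inherits(grm, "grm")) grm$K else as.matrix(grm)
  if (!isSymmetric(unname(K), tol = 1e-6)) stop("GRM must be symmetric")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values))) {
    stop("GRM has substantially negative eigenvalues")
  }
  structure(list(values = pmax(e$values, 0), vectors = e$vectors,
                 ids = rownames(K)),
            class = "grm_eigen")
}

## Reconstruct the kinship for a subset of individuals and re-decompose.
## Used when missing phenotypes force listwise deletion.
subset_eigen <- function(eigen, keep) {
  U <- eigen$vectors
  K <- tcrossprod(sweep(U, 2, eigen$values, `*`), U)
  e <- eigen(K[keep, keep, drop = FALSE], symmetric = TRUE)
  structure(list(values = pmax(e$values, 0), vectors = e$vectors,
                 ids = eigen$ids[keep]),
            class = "grm_eigen")
}
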