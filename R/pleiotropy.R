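#' Local correlation of association statistics between two traits
#'
#' Over variants within `window` bp of the lead (from the trait with the
#' strongest association), keeping only variants significant (p at or below
#' `exclude_p`) in at least one of the two scans, computes the Pearson
#' correlation of t-values and of signed -log10 p-values
#' (`sign(beta) * -log10(p)`). High positive correlation indicates a shared
#' (pleiotropic) signal; strong negative correlation indicates a shared
#' variant with opposite effect directions.
#'
#' @param gwasA,gwasB `gwas_result` objects for the two traits covering the
#'   window.
#' @param lead Lead variant id (the window is centered on its position).
#' @param window Half-width (bp) of the window around the lead.
#' @param exclude_p Variants with p above this in both traits are dropped.
#' @return A `pleiotropy_result`: `traits`, `cor_t`, `cor_signed_logp`,
#'   `n_snps`, `window`, `lead`, `reliable` (FALSE when fewer than 3
#'   variants are retained; correlations are then `NA`), and the retained
#'   per-variant statistics in `$data`.
#' @export
pleiotropy_correlation <- function(gwasA, gwasB, lead, window = 1e6,
                                   exclude_p = 0.05) {
  ia <- match(lead, gwasA$id)
  if (is.na(ia)) stop("lead ", lead, " not in first scan")
  center <- gwasA$pos[ia]
  chrom <- gwasA$chrom[ia]
  a <- gwasA[gwasA$chrom == chrom & abs(gwasA$pos - center) <= window, ,
             drop = FALSE]
  b <- gwasB[match(a$id, gwasB$id), , drop = FALSE]
  ok <- !is.na(a$p) & !is.na(b$p)
  a <- a[ok, ]; b <- b[ok, ]
  keep <- a$p <= exclude_p | b$p <= exclude_p
  a <- a[keep, ]; b <- b[keep, ]
  res <- list(traits = c(attr(gwasA, "trait") %||% "A",
                         attr(gwasB, "trait") %||% "B"),
              n_snps = nrow(a), window = window, lead = lead,
              reliable = nrow(a) >= 3,
              cor_t = NA_real_, cor_signed_logp = NA_real_)
  if (res$reliable) {
    res$cor_t <- stats::cor(a$t, b$t)
    sl <- function(g) sign(g$beta) * (-log10(g$p))
    res$cor_signed_logp <- stats::cor(sl(a), sl(b))
  }
  res$data <- data.frame(id = a$id, pos = a$pos,
                         t_A = a$t, t_B = b$t,
                         p_A = a$p, p_B = b$p, stringsAsFactors = FALSE)
  structure(res, class = "pleiotropy_result")
}

#' @export
print.pleiotropy_result <- function(x, ...) {
  cat(sprintf("Pleiotropy %s vs %s around %s (+/- %g bp): %d SNPs",
              x$traits[1], x$traits[2], x$lead, x$window, x$n_snps))
  if (x$reliable) {
    cat(sprintf("; cor(t) = %.3f, cor(signed -log10 p) = %.3f\n",
                x$cor_t, x$cor_signed_logp))
  } else {
    cat("; too few SNPs, correlations omitted\n")
  }
  invisible(x)
}

#' Pairwise pleiotropy correlation matrix within a region
#'
#' @param gwas_list Named list of `gwas_result` objects (one per trait).
#' @param lead Lead variant id.
#' @param ... Passed to [pleiotropy_correlation()].
#' @return Symmetric matrix of t-value correlations (diagonal 1), with the
#'   signed -log10 p correlations in attribute `"cor_signed_logp"`.
#' @export
pleiotropy_matrix <- function(gwas_list, lead, ...) {
  k <- length(gwas_list)
  M <- diag(1, k); M2 <- diag(1, k)
  dimnames(M) <- dimnames(M2) <- list(names(gwas_list), names(gwas_list))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- pleiotropy_correlation(gwas_list[[i]], gwas_list[[j]], lead, ...)
    M[i, j] <- M[j, i] <- r$cor_t
    M2[i, j] <- M2[j, i] <- r$cor_signed_logp
  }
  attr(M, "cor_signed_logp") <- M2
  M
}
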