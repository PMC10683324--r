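#' Conditional association scan in a region
#'
#' Re-runs the mixed-model scan over a region with candidate variants
#' fitted as fixed-effect covariates. The null variance components are
#' re-estimated with the covariates in the model (cheap at region scale).
#' Covariate variants themselves are excluded from the tested set.
#'
#' @param y Trait deviations aligned with `eigen$ids` (vector for a
#'   single-trait scan, matrix for a multi-trait scan).
#' @param geno A [geno_matrix()].
#' @param eigen A [grm_eigen()].
#' @param covariate_snps Character vector of conditioning variant ids.
#' @param region `list(chrom =, center =, span =)` (span default 10 Mb) or
#'   explicit `list(chrom =, start =, end =)`.
#' @param extra_covariates Optional non-SNP covariate matrix.
#' @return A `gwas_result` or `mt_gwas_result` restricted to the region
#'   (conditioning variants removed), with the refitted null in attribute
#'   `"null"`.
#' @export
conditional_scan <- function(y, geno, eigen, covariate_snps, region,
                             extra_covariates = NULL) {
  if (!is.null(region$center)) {
    span <- region$span %||% 1e7
    region <- list(chrom = region$chrom,
                   start = region$center - span / 2,
                   end = region$center + span / 2)
  }
  covar <- NULL
  if (length(covariate_snps)) {
    covar <- dosage_of(geno, covariate_snps)
    covar[is.na(covar)] <- matrix(colMeans(covar, na.rm = TRUE)[col(covar)],
                                  nrow(covar), ncol(covar))[is.na(covar)]
  }
  X <- cbind(covar, extra_covariates)
  if (is.matrix(y) || is.data.frame(y)) {
    null <- fit_null_mv(as.matrix(y), eigen, covariates = X)
    res <- mt_scan(as.matrix(y), geno, eigen, null, covariates = X,
                   region = region)
  } else {
    null <- fit_null(y, eigen, covariates = X)
    res <- st_scan(y, geno, eigen, null, covariates = X, region = region)
  }
  res <- res[!res$id %in% covariate_snps, , drop = FALSE]
  attr(res, "null") <- null
  attr(res, "covariate_snps") <- covariate_snps
  res
}

#' Iterative conditional mapping rounds
#'
#' Round 1 conditions on the initial candidate variants (coding candidates
#' in the credible set when available, otherwise the lead variants) and
#' scans the region; any new lead exceeding the round threshold is appended
#' to the covariate list and the region is rescanned under the next
#' (typically less stringent, region-calibrated) threshold. A variant can
#' be added as covariate only once. Iteration stops when a round detects no
#' new significant lead or `max_rounds` is reached.
#'
#' @param y Trait deviations (vector).
#' @param geno,eigen See [conditional_scan()].
#' @param region `list(chrom =, center =, span =)`.
#' @param candidates Initial covariate variant ids.
#' @param thresholds Per-round significance thresholds; the last is reused
#'   if more rounds run than thresholds given. Defaults to the
#'   region-calibrated pair `c(2.5e-6, 2e-5)`.
#' @param max_rounds Maximum number of rounds.
#' @param merge_distance Peak-absorption window for new leads (bp).
#' @return List of `conditional_round` objects: `round`, `region`,
#'   `covariates`, `threshold`, `result`, `new_leads`.
#' @export
conditional_rounds <- function(y, geno, eigen, region, candidates,
                               thresholds = c(2.5e-6, 2e-5),
                               max_rounds = 2, merge_distance = 1e6) {
  covars <- unique(candidates)
  rounds <- list()
  for (r in seq_len(max_rounds)) {
    thr <- thresholds[min(r, length(thresholds))]
    res <- conditional_scan(y, geno, eigen, covars, region)
    peaks <- call_qtl(res, thr, merge_distance)
    new_leads <- setdiff(peaks$lead_id, covars)
    rounds[[r]] <- structure(list(round = r, region = region,
                                  covariates = covars, threshold = thr,
                                  result = res, new_leads = new_leads),
                             class = "conditional_round")
    if (!length(new_leads)) break
    covars <- c(covars, new_leads)
  }
  rounds
}

#' @export
print.conditional_round <- function(x, ...) {
  cat(sprintf(
    "Conditional round %d (threshold %.2g): %d covariate(s), %d new lead(s)%s\n",
    x$round, x$threshold, length(x$covariates), length(x$new_leads),
    if (length(x$new_leads)) {
      paste0(" [", paste(x$new_leads, collapse = ", "), "]")
    } else ""))
  invisible(x)
}
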