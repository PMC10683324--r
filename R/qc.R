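new_qc_report <- function(axis, n_input) {
  structure(list(axis = axis, n_input = n_input, n_retained = n_input,
                 filters = list(), thresholds = list(), skipped = character()),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", x$axis, "): ", x$n_input, " in, ", x$n_retained,
      " retained, ", x$n_input - x$n_retained, " removed\n", sep = "")
  for (f in names(x$filters)) {
    cat(sprintf("  %-22s failed: %d\n", f, x$filters[[f]]))
  }
  if (length(x$skipped)) {
    cat("  skipped (metadata absent):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report A `qc_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
qc_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

## 1-df chi-square HWE test on hard genotype counts (n0, n1, n2)
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(NA_real_)
  p <- (n1 + 2 * n2) / (2 * n)
  exp <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  obs <- c(n0, n1, n2)
  ok <- exp > 0
  x2 <- sum((obs[ok] - exp[ok])^2 / exp[ok])
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Variant-level quality control
#'
#' Applies, in order: call rate, minor-allele frequency, Hardy-Weinberg
#' equilibrium (1-df chi-square on hard calls obtained by rounding dosages
#' to the nearest of 0/1/2), Mendelian inconsistencies (opposite homozygotes
#' in parent-offspring pairs), and — when imputation-accuracy metadata is
#' present — post-imputation MAF and accuracy filters. Filters whose
#' required metadata is absent are skipped and logged in the report.
#'
#' @param geno A [geno_matrix()].
#' @param min_call_rate Variants with call rate below this are removed.
#' @param min_maf Minimum minor-allele frequency.
#' @param hwe_p_min Variants with HWE p below this are removed.
#' @param max_mendel Maximum tolerated Mendelian inconsistencies per variant.
#' @param trios Optional data.frame with columns `parent`, `offspring`
#'   (individual ids) defining parent-offspring pairs.
#' @param min_imputed_maf Post-imputation MAF floor (applied only when the
#'   `accuracy` metadata column is present).
#' @param min_accuracy Minimum imputation accuracy (same condition).
#' @return list with elements `geno` (filtered) and `report` (`qc_report`).
#' @export
qc_variants <- function(geno, min_call_rate = 0.95, min_maf = 0.01,
                        hwe_p_min = 0.001, max_mendel = 10, trios = NULL,
                        min_imputed_maf = 0.02, min_accuracy = 0.80) {
  stopifnot(inherits(geno, "geno_matrix"),
            min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf < 0.5, hwe_p_min >= 0, hwe_p_min <= 1)
  d <- geno$dosages
  m <- ncol(d)
  rep <- new_qc_report("variants", m)
  rep$thresholds <- list(min_call_rate = min_call_rate, min_maf = min_maf,
                         hwe_p_min = hwe_p_min, max_mendel = max_mendel,
                         min_imputed_maf = min_imputed_maf,
                         min_accuracy = min_accuracy)
  call_rate <- colMeans(!is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hard <- round(d)
  hwe_p <- vapply(seq_len(m), function(j) {
    h <- hard[, j]
    hwe_chisq_p(sum(h == 0, na.rm = TRUE), sum(h == 1, na.rm = TRUE),
                sum(h == 2, na.rm = TRUE))
  }, numeric(1))

  fail <- list(call_rate = call_rate < min_call_rate,
               maf = maf < min_maf,
               hwe = !is.na(hwe_p) & hwe_p < hwe_p_min)

  if (!is.null(trios)) {
    ip <- match(trios$parent, geno$ids)
    io <- match(trios$offspring, geno$ids)
    if (anyNA(ip) || anyNA(io)) {
      stop("trios reference unknown individual id(s): ",
           paste(unique(c(trios$parent[is.na(ip)],
                          trios$offspring[is.na(io)])), collapse = ", "))
    }
    hp <- hard[ip, , drop = FALSE]
    ho <- hard[io, , drop = FALSE]
    mendel <- colSums((hp == 0 & ho == 2) | (hp == 2 & ho == 0), na.rm = TRUE)
    fail$mendel <- mendel > max_mendel
  } else {
    rep$skipped <- c(rep$skipped, "mendel (no trios)")
  }

  if (!is.null(geno$variants$accuracy)) {
    acc <- geno$variants$accuracy
    fail$imputed_maf <- maf < min_imputed_maf
    fail$accuracy <- !is.na(acc) & acc < min_accuracy
  } else {
    rep$skipped <- c(rep$skipped,
                     "imputed_maf, accuracy (no accuracy metadata)")
  }

  rep$filters <- lapply(fail, sum)
  keep <- !Reduce(`|`, fail)
  rep$n_retained <- sum(keep)
  if (rep$n_retained == 0) warning("all variants removed by QC")
  geno_out <- if (any(keep)) geno[, which(keep)] else {
    structure(list(dosages = d[, 0, drop = FALSE],
                   variants = geno$variants[0, , drop = FALSE],
                   ids = geno$ids), class = "geno_matrix")
  }
  list(geno = geno_out, report = rep)
}

#' Individual-level quality control
#'
#' Removes individuals whose genotyping rate (fraction of non-missing
#' dosages) is lower than `min_genotyping_rate`; a rate exactly equal to the
#' threshold is retained.
#'
#' @param geno A [geno_matrix()].
#' @param min_genotyping_rate Threshold in \[0, 1\].
#' @return list with elements `geno` and `report`.
#' @export
qc_individuals <- function(geno, min_genotyping_rate = 0.90) {
  stopifnot(inherits(geno, "geno_matrix"))
  rate <- rowMeans(!is.na(geno$dosages))
  keep <- rate >= min_genotyping_rate
  if (!any(keep)) stop("all individuals removed by genotyping-rate filter")
  rep <- new_qc_report("individuals", length(keep))
  rep$thresholds <- list(min_genotyping_rate = min_genotyping_rate)
  rep$filters <- list(genotyping_rate = sum(!keep))
  rep$n_retained <- sum(keep)
  list(geno = geno[which(keep), ], report = rep)
}

#' Pre-correct raw phenotypes for age and contemporary group
#'
#' Per trait: residuals of an ordinary least-squares regression on age and
#' age squared, then contemporary-group means are removed so deviations have
#' zero mean within each group. Groups with a single record get deviation 0
#' for that record (logged).
#'
#' @param raw data.frame with `id`, trait columns, and `age` and/or `group`
#'   columns. Traits are every column not named `id`, `age`, `group` unless
#'   given explicitly.
#' @param traits Character vector of trait column names (default: inferred).
#' @param age_col,group_col Column names (set to `NULL` to skip that step).
#' @return data.frame of trait deviations (`id` + corrected traits), with a
#'   `"log"` attribute recording singleton groups.
#' @export
precorrect_phenotypes <- function(raw, traits = NULL, age_col = "age",
                                  group_col = "group") {
  stopifnot(is.data.frame(raw), "id" %in% names(raw))
  if (is.null(traits)) {
    traits <- setdiff(names(raw), c("id", age_col, group_col))
  }
  if (!is.null(age_col) && !age_col %in% names(raw)) {
    stop("age column '", age_col, "' absent")
  }
  out <- data.frame(id = raw$id, stringsAsFactors = FALSE)
  log <- character()
  for (tr in traits) {
    y <- raw[[tr]]
    ok <- !is.na(y)
    if (sum(ok) < 2) stop("trait '", tr, "' has fewer than 2 records")
    dev <- rep(NA_real_, length(y))
    if (!is.null(age_col)) {
      age <- raw[[age_col]]
      fit <- stats::lm(y ~ age + I(age^2), subset = ok)
      dev[ok] <- stats::residuals(fit)
    } else {
      dev[ok] <- y[ok] - mean(y[ok])
    }
    if (!is.null(group_col) && group_col %in% names(raw)) {
      grp <- raw[[group_col]]
      gm <- tapply(dev[ok], grp[ok], mean)
      singles <- names(which(table(grp[ok]) == 1))
      if (length(singles)) {
        log <- c(log, paste0(tr, ": singleton group(s) ",
                             paste(singles, collapse = ","),
                             " set to deviation 0"))
      }
      dev[ok] <- dev[ok] - gm[as.character(grp[ok])]
    } else {
      dev[ok] <- dev[ok] - mean(dev[ok])
    }
    out[[tr]] <- dev
  }
  attr(out, "log") <- log
  out
}
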