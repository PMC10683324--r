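## Exact Poisson-binomial upper tail P(X >= x) by dynamic-programming
## convolution over per-trial success probabilities q
poisson_binomial_tail <- function(x, q) {
  k <- length(q)
  if (x <= 0) return(1)
  if (x > k) return(0)
  pmf <- c(1, rep(0, k))
  for (i in seq_len(k)) {
    pmf <- c(pmf[1] * (1 - q[i]),
             pmf[-1] * (1 - q[i]) + pmf[-(k + 1)] * q[i])
  }
  sum(pmf[(x + 1):(k + 1)])
}

#' Coding-variant enrichment in credible sets
#'
#' Null model: each credible-set member is coding independently with
#' probability `coding_rate`. Tests (i) the total number of coding variants
#' across all sets — exact binomial upper tail on the summed set sizes, and
#' (ii) the number of sets harbouring at least one coding variant — exact
#' Poisson-binomial upper tail over per-set probabilities
#' `1 - (1 - rate)^size`. The Monte Carlo method simulates the same null.
#'
#' @param cs_sizes Integer vector of credible-set member counts.
#' @param coding_rate Genome-wide coding-variant proportion (e.g. 0.0034).
#' @param observed_total Observed number of coding variants across the sets.
#' @param observed_cs_with_coding Optional observed number of sets with at
#'   least one coding variant.
#' @param method `"exact"` or `"monte_carlo"`.
#' @param n_reps Monte Carlo repetitions (default 1e6).
#' @param seed Seed for the Monte Carlo draw.
#' @return An `enrichment_result`: `expected_total`
#'   (`coding_rate * sum(cs_sizes)`), `p_total`, `p_cs_count` (NA when the
#'   per-set count is not supplied), `method`, `n_reps`, `seed`, and Monte
#'   Carlo standard errors when applicable.
#' @export
coding_enrichment <- function(cs_sizes, coding_rate, observed_total,
                              observed_cs_with_coding = NULL,
                              method = c("exact", "monte_carlo"),
                              n_reps = 1e6, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(cs_sizes) >= 1, coding_rate > 0, coding_rate < 1,
            observed_total >= 0)
  total_size <- sum(cs_sizes)
  if (observed_total > total_size) {
    stop("observed_total (", observed_total, ") exceeds total set size (",
         total_size, ")")
  }
  expected_total <- coding_rate * total_size
  q_cs <- 1 - (1 - coding_rate)^cs_sizes
  out <- list(cs_sizes = cs_sizes, coding_rate = coding_rate,
              observed_total = observed_total,
              observed_cs_with_coding = observed_cs_with_coding,
              expected_total = expected_total, method = method,
              n_reps = if (method == "monte_carlo") n_reps else NA,
              seed = if (method == "monte_carlo") seed else NA,
              p_cs_count = NA_real_, se_total = NA_real_,
              se_cs_count = NA_real_)
  if (method == "exact") {
    out$p_total <- stats::pbinom(observed_total - 1, total_size, coding_rate,
                                 lower.tail = FALSE)
    if (!is.null(observed_cs_with_coding)) {
      out$p_cs_count <- poisson_binomial_tail(observed_cs_with_coding, q_cs)
    }
  } else {
    set.seed(seed)
    counts <- matrix(stats::rbinom(n_reps * length(cs_sizes),
                                   size = rep(cs_sizes, each = n_reps),
                                   prob = coding_rate),
                     n_reps, length(cs_sizes))
    tot <- rowSums(counts)
    out$p_total <- mean(tot >= observed_total)
    out$se_total <- sqrt(out$p_total * (1 - out$p_total) / n_reps)
    if (!is.null(observed_cs_with_coding)) {
      with_c <- rowSums(counts > 0)
      out$p_cs_count <- mean(with_c >= observed_cs_with_coding)
      out$se_cs_count <- sqrt(out$p_cs_count * (1 - out$p_cs_count) / n_reps)
    }
  }
  structure(out, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Coding-variant enrichment (%s): %d set(s), %d members, rate %.4g\n",
    x$method, length(x$cs_sizes), sum(x$cs_sizes), x$coding_rate))
  cat(sprintf("  expected coding variants %.2f, observed %d, p = %.3g\n",
              x$expected_total, x$observed_total, x$p_total))
  if (!is.na(x$p_cs_count)) {
    cat(sprintf("  sets with >= 1 coding variant: observed %d, p = %.3g\n",
                x$observed_cs_with_coding, x$p_cs_count))
  }
  invisible(x)
}

#' Tail probability of coding lead variants
#'
#' Upper tail of Binomial(`n_cs`, `coding_rate`) at the observed number of
#' credible sets whose lead variant is coding.
#'
#' @param n_cs Number of credible sets.
#' @param coding_rate Genome-wide coding proportion.
#' @param observed_leads_coding Observed count of coding leads.
#' @return Tail probability.
#' @export
lead_coding_test <- function(n_cs, coding_rate, observed_leads_coding) {
  stopifnot(observed_leads_coding <= n_cs, observed_leads_coding >= 0)
  stats::pbinom(observed_leads_coding - 1, n_cs, coding_rate,
                lower.tail = FALSE)
}

#' Joint mixed-model effects of candidate variants
#'
#' Fits all candidate variants simultaneously as fixed effects in the LMM
#' (variance components re-estimated under the joint model per trait) and
#' returns their effect vector per trait with standard errors.
#'
#' @param Y Trait deviation matrix (or vector for one trait), aligned with
#'   `eigen$ids`.
#' @param geno A [geno_matrix()].
#' @param candidate_ids Variant ids to fit jointly; an error lists the
#'   offending pair when any two have dosage r-squared at or above 0.99.
#' @param eigen A [grm_eigen()].
#' @return A `joint_effects` object: `beta` and `se` matrices (variants x
#'   traits), `candidates`, `null_without`/`null_with` (per-trait lists of
#'   `null_fit`s excluding/including the candidates), `af` (candidate
#'   alternate-allele frequencies).
#' @export
joint_variant_effects <- function(Y, geno, candidate_ids, eigen) {
  Y <- as.matrix(Y)
  Xc <- dosage_of(geno, candidate_ids)
  Xc[is.na(Xc)] <- matrix(colMeans(Xc, na.rm = TRUE)[col(Xc)],
                          nrow(Xc), ncol(Xc))[is.na(Xc)]
  if (length(candidate_ids) > 1) {
    r2 <- stats::cor(Xc)^2
    bad <- which(r2 >= 0.99 & upper.tri(r2), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("collinear candidates (r2 >= 0.99): ",
           paste(candidate_ids[bad[1, 1]], candidate_ids[bad[1, 2]],
                 sep = " / "))
    }
  }
  T <- ncol(Y)
  tn <- colnames(Y) %||% paste0("trait", seq_len(T))
  k <- length(candidate_ids)
  beta <- se <- matrix(NA_real_, k, T, dimnames = list(candidate_ids, tn))
  null_without <- null_with <- vector("list", T)
  for (t in seq_len(T)) {
    y <- Y[, t]
    null_without[[t]] <- fit_null(y, eigen)
    nf <- fit_null(y, eigen, covariates = Xc)
    null_with[[t]] <- nf
    eig <- nf$eigen
    keep <- nf$keep
    U <- eig$vectors
    w <- nf$sigma_g2 * eig$values + nf$sigma_e2
    sw <- 1 / sqrt(w)
    X <- cbind(1, Xc[keep, , drop = FALSE])
    Xs <- crossprod(U, X) * sw
    ys <- crossprod(U, y[keep]) * sw
    XtX <- crossprod(Xs)
    bhat <- solve(XtX, crossprod(Xs, ys))
    r <- ys - Xs %*% bhat
    s2 <- sum(r^2) / (length(ys) - ncol(Xs))
    covb <- solve(XtX) * s2
    beta[, t] <- bhat[-1]
    se[, t] <- sqrt(diag(covb))[-1]
  }
  names(null_without) <- names(null_with) <- tn
  af <- colMeans(Xc, na.rm = TRUE) / 2
  structure(list(beta = beta, se = se, candidates = candidate_ids,
                 null_without = null_without, null_with = null_with,
                 af = af, traits = tn),
            class = "joint_effects")
}

#' Genetic-variance shares of candidate variants
#'
#' Per variant and trait, the share of genetic variance is
#' `2 p (1 - p) beta^2 / sigma_g2`, with `beta` the joint effect, `p` the
#' alternate-allele frequency and `sigma_g2` the polygenic variance from the
#' null model without the candidates. The polygenic-variance reduction is
#' `1 - sigma_g2(with candidates) / sigma_g2(without)`.
#'
#' @param joint A [joint_variant_effects()] result (or explicit pieces via
#'   the other arguments).
#' @param beta,freqs,sigma_g2,sigma_g2_with Used instead of `joint` when it
#'   is `NULL`: effect matrix (variants x traits), allele frequencies,
#'   per-trait polygenic variances without and with candidates fitted.
#' @return A `variance_share` object: `share` (variants x traits),
#'   `aggregate` (per trait), `reduction` (per trait, when the refitted
#'   variances are available).
#' @export
variance_shares <- function(joint = NULL, beta = NULL, freqs = NULL,
                            sigma_g2 = NULL, sigma_g2_with = NULL) {
  if (!is.null(joint)) {
    beta <- joint$beta
    freqs <- joint$af
    sigma_g2 <- vapply(joint$null_without, `[[`, numeric(1), "sigma_g2")
    sigma_g2_with <- vapply(joint$null_with, `[[`, numeric(1), "sigma_g2")
  }
  beta <- as.matrix(beta)
  if (any(sigma_g2 <= 0)) {
    stop("sigma_g2 is zero for trait(s) ",
         paste(which(sigma_g2 <= 0), collapse = ", "),
         "; variance shares undefined")
  }
  var_qtl <- 2 * freqs * (1 - freqs) * beta^2
  share <- sweep(var_qtl, 2, sigma_g2, `/`)
  aggregate <- colSums(share)
  if (any(aggregate > 1 + 0.1)) {
    warning("aggregate variance share exceeds 1 for trait(s) ",
            paste(names(aggregate)[aggregate > 1.1], collapse = ", "))
  }
  reduction <- if (!is.null(sigma_g2_with)) 1 - sigma_g2_with / sigma_g2
  structure(list(share = share, aggregate = aggregate,
                 reduction = reduction, sigma_g2 = sigma_g2),
            class = "variance_share")
}

#' @export
print.variance_share <- function(x, ...) {
  cat("Genetic-variance shares (per variant x trait):\n")
  print(round(100 * x$share, 2))
  cat("aggregate (%):", paste(round(100 * x$aggregate, 2), collapse = ", "),
      "\n")
  if (!is.null(x$reduction)) {
    cat("polygenic-variance reduction (%):",
        paste(round(100 * x$reduction, 2), collapse = ", "), "\n")
  }
  invisible(x)
}
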