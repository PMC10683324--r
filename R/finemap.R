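#' Pairwise LD (r-squared) matrix
#'
#' Squared Pearson correlation of allele dosages over pairwise-complete
#' individuals. Monomorphic variants get `NA` against every partner.
#'
#' @param geno A [geno_matrix()].
#' @param region Optional `list(chrom =, start =, end =)`.
#' @param window Optional half-width (bp) around `center` used with
#'   `chrom`/`center` in `region` instead of explicit bounds.
#' @return An `ld_matrix`: `r2` (with signed `r` kept in attribute `r`),
#'   `ids`, `pos`, `chrom`.
#' @export
ld_matrix <- function(geno, region = NULL, window = NULL) {
  idx <- seq_len(nrow(geno$variants))
  if (!is.null(region)) {
    if (!is.null(window) && !is.null(region$center)) {
      region$start <- region$center - window
      region$end <- region$center + window
    }
    idx <- region_index(geno, region$chrom,
                        region$start %||% -Inf, region$end %||% Inf)
  }
  if (length(idx) < 2) stop("need at least 2 variants for an LD matrix")
  d <- geno$dosages[, idx, drop = FALSE]
  suppressWarnings(r <- stats::cor(d, use = "pairwise.complete.obs"))
  sds <- apply(d, 2, stats::sd, na.rm = TRUE)
  mono <- is.na(sds) | sds == 0
  r[mono, ] <- NA_real_
  r[, mono] <- NA_real_
  diag(r)[!mono] <- 1
  r2 <- r^2
  structure(list(r2 = r2, ids = geno$variants$id[idx],
                 pos = geno$variants$pos[idx],
                 chrom = geno$variants$chrom[idx], r = r),
            class = "ld_matrix")
}

#' LD-based credible set around a lead variant
#'
#' All variants with `r^2 >= r2_min` to the lead (the lead itself always
#' included).
#'
#' @param lead Lead variant id.
#' @param ld An [ld_matrix()].
#' @param r2_min Minimum r-squared (0.90 or 0.80 in standard use).
#' @return A `credible_set` with method tag `"LD90"`/`"LD80"` (or
#'   `"LD<xx>"` for other thresholds).
#' @export
ld_credible_set <- function(lead, ld, r2_min = 0.90) {
  j <- match(lead, ld$ids)
  if (is.na(j)) stop("lead variant ", lead, " not in LD matrix")
  r2l <- ld$r2[, j]
  if (all(is.na(r2l))) stop("lead variant ", lead, " is monomorphic")
  members <- ld$ids[!is.na(r2l) & r2l >= r2_min]
  if (!lead %in% members) members <- c(lead, members)
  ord <- order(match(members, ld$ids))
  members <- members[ord]
  credible_set(method = sprintf("LD%02d", round(100 * r2_min)),
               lead = lead, members = members,
               r2_to_lead = r2l[match(members, ld$ids)],
               span = range(ld$pos[match(members, ld$ids)]),
               chrom = ld$chrom[j])
}

#' Credible-set container
#'
#' @param method `"IBSS"`, `"LD90"`, `"LD80"` or `"MT-merged"`.
#' @param lead Lead variant id (must be a member).
#' @param members Member variant ids.
#' @param pip Optional posterior inclusion probabilities (IBSS).
#' @param r2_to_lead Optional per-member r2 with the lead.
#' @param coverage Target coverage (IBSS; default 0.95).
#' @param span,chrom Optional genomic span/chromosome.
#' @param trait Source trait or trait-group label.
#' @return A `credible_set` list.
#' @export
credible_set <- function(method, lead, members, pip = NULL,
                         r2_to_lead = NULL, coverage = NA_real_,
                         span = NULL, chrom = NULL, trait = NULL) {
  if (!lead %in% members) stop("lead must be a member of its credible set")
  structure(list(method = method, lead = lead, members = members,
                 pip = pip, r2_to_lead = r2_to_lead, coverage = coverage,
                 span = span, chrom = chrom, trait = trait),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat("credible set [", x$method, "] lead ", x$lead, ": ",
      length(x$members), " variant(s)", sep = "")
  if (!is.null(x$pip)) cat(sprintf(", sum PIP %.3f", sum(x$pip)))
  cat("\n")
  invisible(x)
}

## log Bayes factor of a single standardized effect with prior variance V,
## given effect estimate betahat with sampling variance s2
single_effect_lbf <- function(betahat, s2, V) {
  0.5 * log(s2 / (V + s2)) + 0.5 * betahat^2 / s2 * V / (V + s2)
}

#' Fine-map a region by iterative Bayesian stepwise selection (IBSS)
#'
#' Fits a sum-of-single-effects regression to GWAS summary statistics
#' (z-scores plus the in-sample LD matrix) on the standardized scale with
#' residual variance fixed at 1. Each of the `L` single effects has a
#' uniform prior over variants; its prior effect variance is chosen per
#' effect, each iteration, by maximizing the single-effect marginal
#' likelihood over a log-spaced grid in \[0.01, 1\] (variance of y units),
#' with the effect switched off when no positive prior variance beats the
#' null. For each active effect a 95% credible set is the smallest
#' posterior-ordered variant set reaching the coverage; sets whose minimum
#' absolute pairwise dosage correlation is below `purity_min` are discarded.
#'
#' @param z Per-variant z-scores (aligned with `ld$ids`).
#' @param ld An [ld_matrix()] from the same cohort.
#' @param n GWAS sample size.
#' @param L Maximum number of single effects (default 10).
#' @param coverage Credible-set coverage (default 0.95).
#' @param purity_min Minimum absolute pairwise correlation within a reported
#'   set (default 0.5).
#' @param max_iter,tol IBSS convergence controls.
#' @param ridge Added to the LD diagonal before use (0 by default; the
#'   algorithm forms only products with the LD matrix, so this is rarely
#'   needed).
#' @return List of `credible_set` objects (method `"IBSS"`), with the full
#'   per-variant PIP vector in attribute `"pip"` and the per-effect
#'   posterior matrix in attribute `"alpha"`.
#' @export
ibss_finemap <- function(z, ld, n, L = 10, coverage = 0.95,
                         purity_min = 0.5, max_iter = 100, tol = 1e-4,
                         ridge = 0) {
  m <- length(z)
  stopifnot(m == length(ld$ids), n > 2)
  R <- ld$r
  R[is.na(R)] <- 0
  if (ridge > 0) diag(R) <- diag(R) + ridge
  ## sufficient statistics on the standardized scale
  d <- rep(n - 1, m)
  Xty <- z * sqrt(n - 1)
  s2 <- 1 / d                       # sampling variance of betahat, sigma2 = 1
  Vgrid <- exp(seq(log(0.01), log(1), length.out = 20))

  alpha <- matrix(1 / m, L, m)
  mu <- matrix(0, L, m)
  b <- matrix(0, L, m)              # alpha * mu
  Vl <- rep(0.2, L)
  active <- rep(TRUE, L)
  XtXb_tot <- (n - 1) * drop(R %*% colSums(b))

  for (it in seq_len(max_iter)) {
    b_old <- b
    for (l in seq_len(L)) {
      XtXb_tot <- XtXb_tot - (n - 1) * drop(R %*% b[l, ])
      Xtr <- Xty - XtXb_tot
      betahat <- Xtr / d
      ## per-effect prior variance by single-effect marginal likelihood
      liks <- vapply(Vgrid, function(V) {
        lbf <- single_effect_lbf(betahat, s2, V)
        mx <- max(lbf)
        mx + log(mean(exp(lbf - mx)))
      }, numeric(1))
      best <- which.max(liks)
      if (liks[best] <= 0) {
        active[l] <- FALSE
        alpha[l, ] <- 1 / m
        mu[l, ] <- 0
        b[l, ] <- 0
        next
      }
      active[l] <- TRUE
      Vl[l] <- Vgrid[best]
      lbf <- single_effect_lbf(betahat, s2, Vl[l])
      w <- exp(lbf - max(lbf))
      alpha[l, ] <- w / sum(w)
      post_var <- 1 / (1 / Vl[l] + d)
      mu[l, ] <- post_var * Xtr
      b[l, ] <- alpha[l, ] * mu[l, ]
      XtXb_tot <- XtXb_tot + (n - 1) * drop(R %*% b[l, ])
    }
    if (max(abs(b - b_old)) < tol * max(max(abs(b)), 1e-8)) break
  }

  pip <- 1 - apply(1 - alpha, 2, prod)
  sets <- list()
  for (l in which(active)) {
    o <- order(alpha[l, ], decreasing = TRUE)
    k <- which(cumsum(alpha[l, o]) >= coverage)[1]
    if (is.na(k)) k <- m
    mem_idx <- sort(o[seq_len(k)])
    if (length(mem_idx) > 1) {
      sub <- abs(R[mem_idx, mem_idx])
      purity <- min(sub[lower.tri(sub)])
      if (purity < purity_min) next
    }
    lead <- ld$ids[mem_idx[which.max(alpha[l, mem_idx])]]
    sets[[length(sets) + 1L]] <- credible_set(
      method = "IBSS", lead = lead, members = ld$ids[mem_idx],
      pip = pip[mem_idx], coverage = coverage,
      span = range(ld$pos[mem_idx]), chrom = ld$chrom[mem_idx[1]])
    attr(sets[[length(sets)]], "alpha") <- alpha[l, mem_idx]
  }
  attr(sets, "pip") <- stats::setNames(pip, ld$ids)
  attr(sets, "alpha") <- alpha
  sets
}

#' Multi-trait credible set with qualification and merging
#'
#' A trait group's multi-trait scan is used for fine-mapping only when at
#' least one of its traits shows single-trait evidence of association in the
#' region (p below `qualify`). For each qualifying group an LD-based
#' credible set is built around the group's multi-trait lead (smallest Wald
#' p; ties broken by position); when both groups qualify the union of their
#' sets is returned as the merged multi-trait credible set.
#'
#' @param mt_results Named list of `mt_gwas_result` (one per trait group),
#'   already restricted to or covering the region.
#' @param st_min_p Named list (group -> minimum single-trait p in the region
#'   over that group's traits).
#' @param ld An [ld_matrix()] covering the region.
#' @param r2_min LD threshold for the set (default 0.90).
#' @param qualify Qualification p threshold (default 1e-7).
#' @param region Optional `list(chrom =, start =, end =)` restricting the
#'   lead search.
#' @return A `credible_set` with method `"MT-merged"`, or `NULL` when no
#'   group qualifies.
#' @export
mt_credible_set <- function(mt_results, st_min_p, ld, r2_min = 0.90,
                            qualify = 1e-7, region = NULL) {
  stopifnot(length(mt_results) >= 1, !is.null(names(mt_results)))
  qual <- names(mt_results)[vapply(names(mt_results), function(g) {
    !is.na(st_min_p[[g]]) && st_min_p[[g]] < qualify
  }, logical(1))]
  if (!length(qual)) return(NULL)
  sets <- list(); leads <- character(); lead_p <- numeric()
  for (g in qual) {
    r <- mt_results[[g]]
    if (!is.null(region)) {
      r <- r[r$chrom == region$chrom &
               r$pos >= (region$start %||% -Inf) &
               r$pos <= (region$end %||% Inf), , drop = FALSE]
    }
    r <- r[!is.na(r$p) & r$id %in% ld$ids, , drop = FALSE]
    if (nrow(r) == 0) next
    o <- order(r$p, r$pos)
    leads[g] <- r$id[o[1]]
    lead_p[g] <- r$p[o[1]]
    sets[[g]] <- ld_credible_set(leads[g], ld, r2_min)
  }
  if (!length(sets)) return(NULL)
  members <- sort(unique(unlist(lapply(sets, `[[`, "members"))))
  best <- names(sets)[which.min(lead_p[names(sets)])]
  ord <- order(match(members, ld$ids))
  credible_set(method = "MT-merged", lead = leads[[best]],
               members = members[ord],
               r2_to_lead = ld$r2[match(members[ord], ld$ids),
                                  match(leads[[best]], ld$ids)],
               span = range(ld$pos[match(members, ld$ids)]),
               chrom = ld$chrom[1],
               trait = paste(names(sets), collapse = "+"))
}

#' Summarize overlap among credible sets
#'
#' @param cs_list List of `credible_set` objects (typically the sets of all
#'   significant traits in one QTL region, possibly mixing IBSS and
#'   LD-based sets).
#' @return list with `pairwise` (shared-member count matrix),
#'   `global_intersection`, `all_identical`, `share_at_least_one` (every
#'   pair shares a variant), and `ibss_in_ld` (for each IBSS set, whether it
#'   is fully contained in some LD-based set of the list).
#' @export
cs_overlap_summary <- function(cs_list) {
  stopifnot(length(cs_list) >= 2)
  k <- length(cs_list)
  labs <- vapply(seq_len(k), function(i) {
    paste0(cs_list[[i]]$method, ":", cs_list[[i]]$trait %||% i)
  }, character(1))
  mem <- lapply(cs_list, `[[`, "members")
  pw <- matrix(0L, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pw[i, j] <- length(intersect(mem[[i]], mem[[j]]))
  }
  glob <- Reduce(intersect, mem)
  ident <- all(vapply(mem, function(m) setequal(m, mem[[1]]), logical(1)))
  share <- all(pw[lower.tri(pw)] >= 1)
  is_ibss <- vapply(cs_list, function(s) s$method == "IBSS", logical(1))
  is_ld <- vapply(cs_list, function(s) grepl("^LD|^MT", s$method), logical(1))
  ibss_in_ld <- NULL
  if (any(is_ibss) && any(is_ld)) {
    ibss_in_ld <- vapply(which(is_ibss), function(i) {
      any(vapply(which(is_ld), function(j) {
        all(mem[[i]] %in% mem[[j]])
      }, logical(1)))
    }, logical(1))
    names(ibss_in_ld) <- labs[is_ibss]
  }
  list(pairwise = pw, global_intersection = glob,
       all_identical = ident, share_at_least_one = share,
       ibss_in_ld = ibss_in_ld)
}

#' Export credible sets as a tab-delimited table
#'
#' @param cs_list List of `credible_set` objects.
#' @param region Region label stored in the first column.
#' @return data.frame (one row per member) with columns `region`, `method`,
#'   `trait`, `lead`, `member`, `r2_to_lead`, `pip`.
#' @export
cs_table <- function(cs_list, region = NA_character_) {
  if (inherits(cs_list, "credible_set")) cs_list <- list(cs_list)
  do.call(rbind, lapply(cs_list, function(s) {
    data.frame(region = region, method = s$method,
               trait = s$trait %||% NA_character_,
               lead = s$lead, member = s$members,
               r2_to_lead = s$r2_to_lead %||% NA_real_,
               pip = s$pip %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}
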