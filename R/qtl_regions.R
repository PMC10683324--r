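#' Call significant QTL from a genome scan
#'
#' Greedy peak picking: the most significant variant below `threshold`
#' becomes a QTL lead, all significant variants within `merge_distance` of
#' it are absorbed as members, and the procedure repeats on the remainder.
#' Ties on p are broken by lower position.
#'
#' @param gwas A `gwas_result` (or any data.frame with `id`, `chrom`,
#'   `pos`, `p`).
#' @param threshold Genome-wide significance threshold on p.
#' @param merge_distance Absorption window around each lead (bp).
#' @return data.frame of QTL: `lead_id`, `chrom`, `lead_pos`, `lead_p`,
#'   `n_members`, `members` (list column), `span_start`, `span_end`.
#'   Zero rows when nothing is significant.
#' @export
call_qtl <- function(gwas, threshold, merge_distance = 1e6) {
  sig <- gwas[!is.na(gwas$p) & gwas$p <= threshold, , drop = FALSE]
  out <- list()
  while (nrow(sig) > 0) {
    o <- order(sig$p, sig$pos)
    lead <- sig[o[1], ]
    near <- sig$chrom == lead$chrom &
      abs(sig$pos - lead$pos) <= merge_distance
    grp <- sig[near, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      lead_id = lead$id, chrom = lead$chrom, lead_pos = lead$pos,
      lead_p = lead$p, n_members = nrow(grp),
      span_start = min(grp$pos), span_end = max(grp$pos),
      stringsAsFactors = FALSE)
    out[[length(out)]]$members <- list(grp$id)
    sig <- sig[!near, , drop = FALSE]
  }
  if (!length(out)) {
    return(data.frame(lead_id = character(), chrom = numeric(),
                      lead_pos = numeric(), lead_p = numeric(),
                      n_members = integer(), span_start = numeric(),
                      span_end = numeric(),
                      members = I(list()), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Group per-trait QTL into QTL regions (QTLR)
#'
#' Single-linkage merging of QTL across traits: QTL whose lead positions on
#' the same chromosome are at most `merge_distance` apart belong to the same
#' region (the chaining is transitive, so a region can extend beyond
#' `merge_distance`). Within each region, every other trait whose minimum p
#' over the region span is below `suggestive` is recorded as a suggestive
#' trait. Regions are labelled `"chrom:Mb"` of their most significant lead.
#'
#' @param qtl_by_trait Named list (trait -> [call_qtl()] output).
#' @param merge_distance Lead-to-lead linkage distance (bp).
#' @param suggestive Suggestive p threshold (default 1e-7).
#' @param gwas_all Optional named list (trait -> scan result) used to find
#'   suggestive traits.
#' @return List of `qtl_region` objects: `label`, `chrom`, `span`,
#'   `leads` (per-trait lead table), `traits_significant`,
#'   `traits_suggestive`, `members`.
#' @export
build_qtlr <- function(qtl_by_trait, merge_distance = 1e6,
                       suggestive = 1e-7, gwas_all = NULL) {
  tabs <- lapply(names(qtl_by_trait), function(tr) {
    q <- qtl_by_trait[[tr]]
    if (nrow(q) == 0) return(NULL)
    q$trait <- tr
    q
  })
  tabs <- Filter(Negate(is.null), tabs)
  if (!length(tabs)) return(list())
  all_q <- do.call(rbind, tabs)
  all_q <- all_q[order(all_q$chrom, all_q$lead_pos), , drop = FALSE]

  ## single-linkage chaining of sorted leads per chromosome
  cl <- integer(nrow(all_q)); cur <- 0L
  for (i in seq_len(nrow(all_q))) {
    if (i == 1 || all_q$chrom[i] != all_q$chrom[i - 1] ||
        all_q$lead_pos[i] - all_q$lead_pos[i - 1] > merge_distance) {
      cur <- cur + 1L
    }
    cl[i] <- cur
  }
  regions <- lapply(split(seq_len(nrow(all_q)), cl), function(idx) {
    q <- all_q[idx, , drop = FALSE]
    best <- which.min(q$lead_p)
    span <- c(min(q$span_start), max(q$span_end))
    sig_traits <- sort(unique(q$trait))
    sugg <- character()
    if (!is.null(gwas_all)) {
      for (tr in setdiff(names(gwas_all), sig_traits)) {
        g <- gwas_all[[tr]]
        inr <- g$chrom == q$chrom[1] & g$pos >= span[1] & g$pos <= span[2] &
          !is.na(g$p)
        if (any(inr) && min(g$p[inr]) < suggestive) sugg <- c(sugg, tr)
      }
    }
    structure(list(
      label = sprintf("%s:%d Mb", q$chrom[1], round(q$lead_pos[best] / 1e6)),
      chrom = q$chrom[1], span = span,
      leads = q[, c("trait", "lead_id", "lead_pos", "lead_p")],
      traits_significant = sig_traits,
      traits_suggestive = sort(sugg),
      members = sort(unique(unlist(q$members)))),
      class = "qtl_region")
  })
  names(regions) <- vapply(regions, `[[`, character(1), "label")
  unname(regions)
}

#' @export
print.qtl_region <- function(x, ...) {
  cat("QTLR ", x$label, " [", x$span[1], "-", x$span[2], "]: ",
      length(x$traits_significant), " significant trait(s) (",
      paste(x$traits_significant, collapse = ", "), ")",
      if (length(x$traits_suggestive)) {
        paste0("; suggestive: ", paste(x$traits_suggestive, collapse = ", "))
      } else "", "; ", length(x$members), " member variant(s)\n", sep = "")
  invisible(x)
}

#' Flag variants overlapping BED intervals
#'
#' BED intervals are 0-based half-open, so interval `[start, end)` covers
#' 1-based positions `start+1 .. end`.
#'
#' @param variants data.frame with `chrom` and `pos` (1-based), or a
#'   `credible_set` (its members are looked up in `geno`).
#' @param bed data.frame from [read_bed()].
#' @return Logical vector, one flag per variant.
#' @export
flag_overlap <- function(variants, bed) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  if (nrow(bed) == 0) return(rep(FALSE, nrow(variants)))
  vapply(seq_len(nrow(variants)), function(i) {
    any(bed$chrom == variants$chrom[i] &
          variants$pos[i] > bed$start & variants$pos[i] <= bed$end)
  }, logical(1))
}
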