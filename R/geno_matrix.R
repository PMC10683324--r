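#' Genotype matrix container
#'
#' Bundles an individuals-by-variants allele-dosage matrix with per-variant
#' metadata. Dosages are expected alternate-allele counts in \[0, 2\]
#' (fractional after imputation); missing genotypes are `NA`, never an
#' in-range number.
#'
#' @param dosages Numeric matrix, individuals in rows, variants in columns.
#'   Row names are individual ids, column names variant ids (both assigned
#'   if absent).
#' @param variants `data.frame` with one row per variant and columns `id`,
#'   `chrom`, `pos` (1-based bp), `ref`, `alt`; optional `af`
#'   (alternate-allele frequency, recomputed when absent) and `accuracy`
#'   (imputation accuracy in \[0, 1\]).
#'
#' @return An object of class `geno_matrix`: a list with elements `dosages`,
#'   `variants` and `ids`.
#' @export
geno_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (ncol(dosages) != nrow(variants)) {
    stop("dosage columns (", ncol(dosages), ") and variant rows (",
         nrow(variants), ") differ")
  }
  req <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(variants$id)) stop("duplicated variant ids")
  if (any(!is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) {
      stop("dosages outside [0, 2]; missing values must be NA")
    }
  }
  ord <- order(variants$chrom, variants$pos)
  if (is.unsorted(ord, strictly = FALSE) || any(ord != seq_along(ord))) {
    variants <- variants[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
  }
  by_chr <- split(variants$pos, variants$chrom)
  if (any(vapply(by_chr, function(p) any(diff(p) <= 0), logical(1)))) {
    stop("variant positions must be strictly increasing within chromosome")
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  }
  colnames(dosages) <- variants$id
  if (is.null(variants$af)) {
    variants$af <- colMeans(dosages, na.rm = TRUE) / 2
  }
  rownames(variants) <- NULL
  structure(list(dosages = dosages, variants = variants,
                 ids = rownames(dosages)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$ids), "individuals x",
      nrow(x$variants), "variants on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  maf <- pmin(x$variants$af, 1 - x$variants$af)
  cat(sprintf("  MAF: median %.3f, range [%.3f, %.3f]\n",
              stats::median(maf), min(maf), max(maf)))
  if (anyNA(x$dosages)) {
    cat(sprintf("  missing dosages: %.2f%%\n", 100 * mean(is.na(x$dosages))))
  }
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param i Individual selector (indices, logical, or ids).
#' @param j Variant selector (indices, logical, or variant ids).
#' @param ... Ignored.
#' @return A `geno_matrix` restricted to the selected individuals/variants.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$ids)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(j)) j <- match(j, x$variants$id)
  if (anyNA(j)) stop("unknown variant id in subset")
  d <- x$dosages[i, j, drop = FALSE]
  v <- x$variants[j, , drop = FALSE]
  v$af <- colMeans(d, na.rm = TRUE) / 2
  geno_matrix(d, v)
}

#' Locate variants inside a genomic region
#'
#' @param geno A [geno_matrix()].
#' @param chrom Chromosome id.
#' @param start,end 1-based inclusive bounds (bp).
#' @return Integer indices of variants within the region, in position order.
#' @export
region_index <- function(geno, chrom, start = -Inf, end = Inf) {
  v <- geno$variants
  which(v$chrom == chrom & v$pos >= start & v$pos <= end)
}

#' Extract dosage columns by variant id
#'
#' @param geno A [geno_matrix()].
#' @param ids Variant ids.
#' @return Numeric matrix (individuals x length(ids)).
#' @export
dosage_of <- function(geno, ids) {
  j <- match(ids, geno$variants$id)
  if (anyNA(j)) stop("unknown variant id(s): ",
                     paste(ids[is.na(j)], collapse = ", "))
  geno$dosages[, j, drop = FALSE]
}
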