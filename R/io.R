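#' Read a genotype matrix from VCF or TSV
#'
#' For VCF input the `DS` (dosage) FORMAT field is preferred when present;
#' otherwise `GT` is converted to an alternate-allele count. Multi-allelic
#' records are excluded with a warning (their count is retained in the
#' returned object's `"excluded_multiallelic"` attribute). For TSV input the
#' file must have a header row with columns `id`, `chrom`, `pos`, `ref`,
#' `alt`, optionally `accuracy`, followed by one column per individual;
#' missing dosages are empty cells or `.`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2) stop("VCF has no sample columns: ", path)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    warning(n_multi, " multi-allelic record(s) excluded")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic records in ", path)
  has_ds <- any(grepl("(^|:)DS(:|$)", vcf@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- gt_to_dosage(gt)
    if (is.null(dim(ds))) {
      ds <- matrix(ds, nrow = nrow(fix),
                   dimnames = list(NULL, colnames(gt)))
    }
  }
  dosages <- t(ds)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  vars <- data.frame(id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  acc <- extract_info_num(fix$INFO, "AR2")
  if (any(!is.na(acc))) vars$accuracy <- acc
  suppressWarnings(vars$chrom_num <- as.numeric(vars$chrom))
  if (!anyNA(vars$chrom_num)) vars$chrom <- vars$chrom_num
  vars$chrom_num <- NULL
  g <- geno_matrix(dosages, vars)
  attr(g, "excluded_multiallelic") <- n_multi
  g
}

gt_to_dosage <- function(gt) {
  conv <- function(x) {
    x[x %in% c(".", "./.", ".|.", "")] <- NA
    a <- strsplit(x, "[/|]")
    vapply(a, function(al) {
      if (length(al) == 0 || anyNA(al) || any(al == "."))
        return(NA_real_)
      sum(al != "0")
    }, numeric(1))
  }
  apply(gt, 2, conv)
}

extract_info_num <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
  out <- rep(NA_real_, length(info))
  hit <- grepl(paste0("(^|;)", key, "="), info)
  out[hit] <- as.numeric(sub(paste0(".*", key, "="), "", m))
  out
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = c("", ".", "NA"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("TSV lacks column(s): ", paste(miss, collapse = ", "))
  meta_cols <- intersect(c(req, "accuracy", "af"), names(tab))
  ind_cols <- setdiff(names(tab), meta_cols)
  if (length(ind_cols) == 0) stop("TSV has no sample columns: ", path)
  dosages <- t(as.matrix(tab[, ind_cols, drop = FALSE]))
  bad <- which(!is.na(dosages) & (dosages < 0 | dosages > 2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("malformed dosage at data line ", bad[1, 2] + 1L,
         " (variant ", tab$id[bad[1, 2]], "): value out of [0, 2]")
  }
  rownames(dosages) <- ind_cols
  geno_matrix(dosages, tab[, meta_cols, drop = FALSE])
}

#' Write a genotype matrix to VCF or TSV
#'
#' VCF output carries both `GT` (dosages rounded to the nearest of 0/1/2)
#' and `DS` (the dosage itself) FORMAT fields; missing dosages are emitted
#' as `./.:.`. TSV output mirrors the layout accepted by
#' [read_genotypes()].
#'
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  v <- geno$variants
  if (format == "tsv") {
    tab <- data.frame(v[, intersect(c("id", "chrom", "pos", "ref", "alt",
                                      "accuracy"), names(v))],
                      t(geno$dosages), check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
    return(invisible(path))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           if (!is.null(v$accuracy))
             "##INFO=<ID=AR2,Number=1,Type=Float,Description=\"Imputation accuracy\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", geno$ids), collapse = "\t"))
  hard <- round(geno$dosages)
  gt_codes <- c("0/0", "0/1", "1/1")
  lines <- vapply(seq_len(nrow(v)), function(j) {
    d <- geno$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[hard[, j] + 1L])
    ds <- ifelse(is.na(d), ".", formatC(d, format = "g", digits = 6))
    info <- if (!is.null(v$accuracy) && !is.na(v$accuracy[j])) {
      paste0("AR2=", v$accuracy[j])
    } else "."
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            info, "GT:DS", paste(gt, ds, sep = ":")), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-delimited with a header; must contain an `id` column, trait columns,
#' and optionally `age` and `group` columns for pre-correction.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = c("", "NA", "."),
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(tab)) stop("phenotype table lacks an 'id' column")
  if (anyDuplicated(tab$id)) stop("duplicated individual ids in ", path)
  tab
}

#' Write a tab-delimited table
#'
#' @param x A data.frame (phenotypes, annotations, GWAS results, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a BED interval file
#'
#' Standard BED coordinates: 0-based, half-open `[start, end)`. The
#' interval therefore covers 1-based positions `start+1 .. end`.
#'
#' @param path File path (at least 3 tab-separated columns, no header).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3) stop("malformed BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(p[2])); e <- suppressWarnings(as.numeric(p[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s) {
      stop("malformed BED line ", i, ": bad coordinates '", p[2], "', '",
           p[3], "'")
    }
  }
  chrom <- vapply(parts, `[`, character(1), 1)
  suppressWarnings(cn <- as.numeric(chrom))
  if (!anyNA(cn)) chrom <- cn
  data.frame(chrom = chrom,
             start = vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
             end = vapply(parts, function(p) as.numeric(p[3]), numeric(1)),
             stringsAsFactors = FALSE)
}
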