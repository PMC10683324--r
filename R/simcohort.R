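#' Specify a simulated quantitative trait locus
#'
#' @param chrom Chromosome id (integer-like).
#' @param position 1-based position (bp); a variant is planted there.
#' @param effects Numeric vector of additive effects, one per trait
#'   (trait units per alternate-allele dose).
#' @param recessive_penalty Optional scalar added to every trait of
#'   homozygous-alternate carriers; negative values model recessive
#'   deleterious alleles kept frequent by a favourable additive effect
#'   (heterozygote advantage).
#' @param frequency_target Founder alternate-allele frequency for the
#'   planted variant.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(chrom, position, effects, recessive_penalty = 0,
                     frequency_target = 0.3) {
  stopifnot(length(position) == 1, position >= 1,
            is.numeric(effects), length(recessive_penalty) == 1,
            frequency_target > 0, frequency_target < 1)
  structure(list(chrom = chrom, position = as.integer(position),
                 effects = as.numeric(effects),
                 recessive_penalty = recessive_penalty,
                 frequency_target = frequency_target),
            class = "qtl_spec")
}

check_psd <- function(M, label) {
  if (!isSymmetric(unname(M), tol = 1e-8)) stop(label, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(label, " must be positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  }
  invisible(TRUE)
}

#' Configure a synthetic cohort simulation
#'
#' Defines a diploid cohort whose genotypes are haplotype mosaics of a
#' founder panel (giving distance-decaying LD), with correlated polygenic
#' trait deviations, planted pleiotropic QTL, and VEP-style variant
#' annotations.
#'
#' @param n_individuals Cohort size.
#' @param n_chromosomes Number of chromosomes.
#' @param n_variants_per_chrom Variants simulated per chromosome (before the
#'   MAF floor is applied).
#' @param n_founder_haplotypes Size of the founder haplotype panel; larger
#'   panels give weaker background LD.
#' @param mean_spacing_bp Average inter-variant distance (bp).
#' @param block_length_bp Target LD-block length (bp); used to derive
#'   `switch_rate` when the latter is `NULL`.
#' @param switch_rate Per-variant probability that a haplotype switches the
#'   founder it is copying. `0` forces complete LD along the chromosome.
#' @param founder_ld_decay_bp Decay length (bp) of the latent AR(1) process
#'   that correlates founder alleles along the chromosome: adjacent variants
#'   separated by `d` bp have latent correlation `exp(-d / decay)`. This is
#'   what gives the panel (and hence the cohort) LD blocks; `0` makes
#'   founder alleles independent across variants, in which case population
#'   LD reduces to founder-identity sharing of order `1/n_founder_haplotypes`.
#' @param maf_floor Variants with realized minor-allele frequency below this
#'   are dropped (planted QTL variants are kept).
#' @param traits Character vector of trait names (length `T`).
#' @param Vg,Ve `T x T` genetic and residual covariance matrices
#'   (trait units squared); both must be symmetric positive semi-definite.
#' @param qtl_spec List of [qtl_spec()] objects.
#' @param coding_rate Genome-wide probability that a variant is coding
#'   (MODERATE/HIGH impact). Default 0.0034, a typical sequence-level rate.
#' @param dosage_noise_sd If positive, Gaussian noise of this SD is added to
#'   hard genotype calls and the result clipped to \[0, 2\], emulating
#'   fractional imputed dosages.
#' @param seed Integer seed; the full simulation is reproducible given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_individuals = 1000,
                       n_chromosomes = 2,
                       n_variants_per_chrom = 500,
                       n_founder_haplotypes = 100,
                       mean_spacing_bp = 10000,
                       block_length_bp = NULL,
                       switch_rate = 0.1,
                       founder_ld_decay_bp = 100000,
                       maf_floor = 0.01,
                       traits = c("trait1", "trait2"),
                       Vg = diag(0.35, length(traits)),
                       Ve = diag(0.65, length(traits)),
                       qtl_spec = list(),
                       coding_rate = 0.0034,
                       dosage_noise_sd = 0,
                       seed = 1L) {
  if (n_founder_haplotypes < 1) stop("need at least one founder haplotype")
  if (is.null(switch_rate)) {
    if (is.null(block_length_bp)) stop("give switch_rate or block_length_bp")
    switch_rate <- min(1, mean_spacing_bp / block_length_bp)
  }
  stopifnot(n_individuals >= 1, n_chromosomes >= 1,
            n_variants_per_chrom >= 1,
            switch_rate >= 0, switch_rate <= 1,
            founder_ld_decay_bp >= 0,
            maf_floor > 0, maf_floor < 0.5,
            coding_rate >= 0, coding_rate <= 1,
            dosage_noise_sd >= 0)
  T <- length(traits)
  Vg <- as.matrix(Vg); Ve <- as.matrix(Ve)
  if (!all(dim(Vg) == T) || !all(dim(Ve) == T)) {
    stop("Vg and Ve must be ", T, "x", T, " for ", T, " traits")
  }
  check_psd(Vg, "Vg"); check_psd(Ve, "Ve")
  span <- n_variants_per_chrom * mean_spacing_bp * 2
  for (q in qtl_spec) {
    if (!inherits(q, "qtl_spec")) stop("qtl_spec must be a list of qtl_spec()")
    if (length(q$effects) != T) {
      stop("QTL effects length ", length(q$effects), " != ", T, " traits")
    }
    if (!(q$chrom %in% seq_len(n_chromosomes)) || q$position > span) {
      stop("QTL at ", q$chrom, ":", q$position,
           " outside simulated coordinate range (chrom 1..", n_chromosomes,
           ", pos 1..", span, ")")
    }
  }
  structure(list(n_individuals = n_individuals,
                 n_chromosomes = n_chromosomes,
                 n_variants_per_chrom = n_variants_per_chrom,
                 n_founder_haplotypes = n_founder_haplotypes,
                 mean_spacing_bp = mean_spacing_bp,
                 block_length_bp = block_length_bp,
                 switch_rate = switch_rate,
                 founder_ld_decay_bp = founder_ld_decay_bp,
                 maf_floor = maf_floor,
                 traits = traits, Vg = Vg, Ve = Ve,
                 qtl_spec = qtl_spec, coding_rate = coding_rate,
                 dosage_noise_sd = dosage_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Founder haplotype panel for one chromosome. Alleles are thresholded from
## a latent AR(1) Gaussian process along the variant positions, so marginal
## frequencies are exact while the panel carries distance-decaying LD
## (decay_bp = 0 gives independent columns).
founder_panel <- function(n_founders, freq, pos, decay_bp) {
  m <- length(freq)
  Z <- matrix(stats::rnorm(n_founders * m), n_founders, m)
  if (decay_bp > 0 && m > 1) {
    rho <- exp(-diff(pos) / decay_bp)
    for (j in 2:m) {
      Z[, j] <- rho[j - 1] * Z[, j - 1] +
        sqrt(1 - rho[j - 1]^2) * Z[, j]
    }
  }
  matrix(as.integer(Z < rep(stats::qnorm(freq), each = n_founders)),
         n_founders, m)
}

## founder-id matrix for one chromosome: haplotypes copy a founder and switch
## with probability switch_rate at each variant
mosaic_founder_ids <- function(n_hap, m, n_founders, switch_rate) {
  S <- matrix(stats::rbinom(n_hap * m, 1L, switch_rate), n_hap, m)
  S[, 1] <- 1L
  draws <- matrix(sample.int(n_founders, n_hap * m, replace = TRUE), n_hap, m)
  lastpos <- t(apply(sweep(S, 2, seq_len(m), `*`), 1, cummax))
  matrix(draws[cbind(rep(seq_len(n_hap), m), as.vector(lastpos))], n_hap, m)
}

#' Simulate LD-structured diploid genotypes
#'
#' Each individual carries two haplotypes per chromosome, built by mosaic
#' copying from a panel of founder haplotypes. Founder allele frequencies
#' are drawn from a U(0.05, 0.95) spectrum and the panel carries
#' distance-decaying LD from a latent AR(1) process
#' (`founder_ld_decay_bp`), which the mosaic copying (switch probability
#' `switch_rate` per variant) transfers to the cohort. Variants listed in
#' `config$qtl_spec` are planted at their positions with the requested
#' founder frequency and are exempt from the MAF floor.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] of hard-call dosages in `{0, 1, 2}` (fractional
#'   if `dosage_noise_sd > 0`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  H <- config$n_founder_haplotypes
  dos_list <- list(); var_list <- list()
  for (chr in seq_len(config$n_chromosomes)) {
    qtl_here <- Filter(function(q) q$chrom == chr, config$qtl_spec)
    qtl_pos <- vapply(qtl_here, `[[`, integer(1), "position")
    m0 <- config$n_variants_per_chrom - length(qtl_pos)
    span <- config$n_variants_per_chrom * config$mean_spacing_bp
    pos <- sort(sample(setdiff(seq_len(span), qtl_pos), m0))
    pos <- sort(c(pos, qtl_pos))
    m <- length(pos)
    freq <- stats::runif(m, 0.05, 0.95)
    is_qtl <- pos %in% qtl_pos
    for (q in qtl_here) freq[pos == q$position] <- q$frequency_target
    founders <- founder_panel(H, freq, pos, config$founder_ld_decay_bp)
    fid <- mosaic_founder_ids(2L * n, m, H, config$switch_rate)
    hap <- matrix(founders[cbind(as.vector(fid), rep(seq_len(m), each = 2L * n))],
                  2L * n, m)
    dos <- hap[seq_len(n), , drop = FALSE] + hap[n + seq_len(n), , drop = FALSE]
    af <- colMeans(dos) / 2
    keep <- pmin(af, 1 - af) >= config$maf_floor | is_qtl
    dos_list[[chr]] <- dos[, keep, drop = FALSE]
    var_list[[chr]] <- data.frame(
      id = paste0(chr, ":", pos[keep]),
      chrom = chr, pos = pos[keep],
      ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  dosages <- do.call(cbind, dos_list)
  storage.mode(dosages) <- "double"
  if (config$dosage_noise_sd > 0) {
    dosages <- pmin(pmax(dosages +
      stats::rnorm(length(dosages), 0, config$dosage_noise_sd), 0), 2)
  }
  rownames(dosages) <- sprintf("ind%04d", seq_len(n))
  geno_matrix(dosages, do.call(rbind, var_list))
}

## PSD square root via eigendecomposition (works for rank-deficient V)
sqrt_psd <- function(V) {
  e <- eigen(V, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate trait deviations on a genotyped cohort
#'
#' Phenotypes follow `Y = sum_q x_q effects_q' + g + e`: planted QTL act
#' additively (plus an optional recessive penalty on homozygous-alternate
#' carriers), the polygenic term `g` is a scaled sum over all non-QTL
#' (background) variants so that a GRM built from the same markers is
#' internally consistent, and `e` is multivariate normal residual noise.
#' The realized sample covariance of `g` is scaled to equal `config$Vg`
#' exactly, making heritability recovery testable.
#'
#' @param geno A [geno_matrix()] from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return A list with `phenotypes` (data.frame: `id` plus one column per
#'   trait) and `truth` (a `sim_truth` list: causal table, `g`, `e`,
#'   realized covariances).
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- length(geno$ids)
  T <- length(config$traits)
  qtl_ids <- vapply(config$qtl_spec, function(q) {
    id <- paste0(q$chrom, ":", q$position)
    if (!id %in% geno$variants$id) {
      stop("QTL position ", q$chrom, ":", q$position,
           " absent from genotype matrix")
    }
    id
  }, character(1))

  Y <- matrix(0, n, T, dimnames = list(geno$ids, config$traits))
  ## polygenic background over non-QTL variants
  g <- matrix(0, n, T)
  if (any(config$Vg != 0)) {
    bg <- setdiff(geno$variants$id, qtl_ids)
    W <- scale(geno$dosages[, bg, drop = FALSE])
    W[is.na(W)] <- 0
    Z <- matrix(stats::rnorm(length(bg) * T), length(bg), T)
    g0 <- W %*% Z
    C0 <- stats::cov(g0)
    g <- g0 %*% solve(chol(C0)) %*% sqrt_psd(config$Vg)
    g <- sweep(g, 2, colMeans(g))
  }
  e <- matrix(stats::rnorm(n * T), n, T) %*% sqrt_psd(config$Ve)
  Y <- Y + g + e
  for (i in seq_along(config$qtl_spec)) {
    q <- config$qtl_spec[[i]]
    x <- geno$dosages[, match(qtl_ids[i], geno$variants$id)]
    Y <- Y + tcrossprod(x, q$effects)
    if (q$recessive_penalty != 0) {
      hom <- !is.na(x) & x >= 1.5
      Y[hom, ] <- Y[hom, ] + q$recessive_penalty
    }
  }
  causal <- data.frame(
    id = qtl_ids,
    chrom = vapply(config$qtl_spec, function(q) q$chrom, numeric(1)),
    pos = vapply(config$qtl_spec, function(q) q$position, numeric(1)),
    recessive_penalty = vapply(config$qtl_spec, `[[`, numeric(1),
                               "recessive_penalty"),
    frequency_target = vapply(config$qtl_spec, `[[`, numeric(1),
                              "frequency_target"),
    stringsAsFactors = FALSE)
  effects <- do.call(rbind, lapply(config$qtl_spec, `[[`, "effects"))
  if (!is.null(effects)) colnames(effects) <- config$traits
  truth <- structure(list(causal = causal, effects = effects,
                          g = g, e = e,
                          Vg_realized = stats::cov(g),
                          Ve_realized = stats::cov(e)),
                     class = "sim_truth")
  phen <- data.frame(id = geno$ids, Y, stringsAsFactors = FALSE,
                     row.names = NULL, check.names = FALSE)
  list(phenotypes = phen, truth = truth)
}

#' Simulate VEP-style variant annotations
#'
#' Flags each variant as coding (MODERATE or HIGH impact) independently
#' with probability `coding_rate`; the remainder are MODIFIER/LOW.
#'
#' @param geno A [geno_matrix()].
#' @param coding_rate Per-variant coding probability.
#' @param seed Integer seed.
#' @param force_coding Variant ids forced to be coding (e.g. planted causal
#'   missense variants).
#' @return A data.frame with columns `id`, `consequence`, `impact`, `gene`,
#'   `sift` and logical `coding`.
#' @export
simulate_annotations <- function(geno, coding_rate = 0.0034, seed = 1L,
                                 force_coding = character()) {
  stopifnot(coding_rate >= 0, coding_rate <= 1)
  set.seed(seed)
  v <- geno$variants
  m <- nrow(v)
  coding <- stats::runif(m) < coding_rate
  coding[v$id %in% force_coding] <- TRUE
  impact <- ifelse(coding,
                   ifelse(stats::runif(m) < 0.9, "MODERATE", "HIGH"),
                   ifelse(stats::runif(m) < 0.2, "LOW", "MODIFIER"))
  consequence <- c(MODIFIER = "intergenic_variant",
                   LOW = "synonymous_variant",
                   MODERATE = "missense_variant",
                   HIGH = "stop_gained")[impact]
  sift <- ifelse(impact == "MODERATE",
                 round(stats::runif(m, 0, 0.2), 3), NA_real_)
  data.frame(id = v$id, consequence = unname(consequence), impact = impact,
             gene = paste0("GENE", v$chrom, "_", v$pos %/% 1e6),
             sift = sift, coding = coding, stringsAsFactors = FALSE)
}

#' Cattle-like multi-trait cohort preset
#'
#' A configuration emulating the structure of a beef-cattle mapping cohort:
#' eleven conformation traits in two blocks (six body-dimension traits, five
#' muscular-development traits) with positive genetic correlations within
#' blocks and negative correlations between them, moderate heritability, a
#' pleiotropic QTL with opposite-signed effects on the two blocks, and a
#' frequent recessive deleterious variant whose additive effect on muscling
#' is favourable (heterozygote advantage).
#'
#' @param n_individuals Cohort size (default 1500; desk-scale).
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
cattle_cohort_config <- function(n_individuals = 1500, seed = 1L) {
  traits <- c("height", "length", "pelvis_length", "pelvis_width",
              "chest_width", "rib_shape", "rump", "top_muscling",
              "shoulder_muscling", "buttock_side", "buttock_rear")
  T <- length(traits)
  size <- 1:6; musc <- 7:11
  Rg <- diag(T)
  Rg[size, size] <- 0.5; Rg[musc, musc] <- 0.5
  Rg[size, musc] <- -0.25; Rg[musc, size] <- -0.25
  diag(Rg) <- 1
  h2 <- 0.35
  Vg <- h2 * Rg
  Re <- diag(T); Re[size, size] <- 0.2; Re[musc, musc] <- 0.2; diag(Re) <- 1
  Ve <- (1 - h2) * Re
  eff <- numeric(T)
  eff[size] <- 0.30; eff[musc] <- -0.25
  eff2 <- numeric(T); eff2[musc] <- 0.30
  sim_config(
    n_individuals = n_individuals,
    n_chromosomes = 3,
    n_variants_per_chrom = 600,
    n_founder_haplotypes = 40,
    mean_spacing_bp = 10000,
    switch_rate = 0.08,
    traits = traits, Vg = Vg, Ve = Ve,
    qtl_spec = list(
      qtl_spec(1, 2000000, eff, frequency_target = 0.3),
      qtl_spec(2, 3000000, eff2, recessive_penalty = -1.5,
               frequency_target = 0.25)),
    coding_rate = 0.0034,
    seed = seed)
}
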