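## Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## single-trait cohort with two planted QTL on chromosome 1 and a clean
## (other-chromosome) GRM; used by scan, region and conditional tests
st_cohort <- function() {
  cfg <- sim_config(
    n_individuals = 1200, n_chromosomes = 2, n_variants_per_chrom = 300,
    n_founder_haplotypes = 80, switch_rate = 0.15,
    traits = "y", Vg = matrix(0.3), Ve = matrix(0.7),
    qtl_spec = list(qtl_spec(1, 1000000, 0.45, frequency_target = 0.35),
                    qtl_spec(1, 2200000, 0.45, frequency_target = 0.40)),
    seed = 33)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  eig <- grm_eigen(compute_grm(geno,
                               marker_subset = which(geno$variants$chrom == 2)))
  y <- sim$phenotypes$y
  null <- fit_null(y, eig)
  list(cfg = cfg, geno = geno, y = y, truth = sim$truth, eigen = eig,
       null = null,
       scan = st_scan(y, geno, eig, null, trait = "y"))
}

## two traits with one opposite-sign pleiotropic QTL
mt_cohort <- function() {
  Vg <- 0.3 * matrix(c(1, -0.5, -0.5, 1), 2)
  Ve <- 0.7 * diag(2)
  cfg <- sim_config(
    n_individuals = 1200, n_chromosomes = 2, n_variants_per_chrom = 300,
    n_founder_haplotypes = 80, switch_rate = 0.15,
    traits = c("t1", "t2"), Vg = Vg, Ve = Ve,
    qtl_spec = list(qtl_spec(1, 1500000, c(0.45, -0.45),
                             frequency_target = 0.35)),
    seed = 44)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  eig <- grm_eigen(compute_grm(geno,
                               marker_subset = which(geno$variants$chrom == 2)))
  Y <- as.matrix(sim$phenotypes[, c("t1", "t2")])
  scans <- lapply(1:2, function(t) {
    st_scan(Y[, t], geno, eig, fit_null(Y[, t], eig),
            trait = colnames(Y)[t])
  })
  names(scans) <- colnames(Y)
  list(cfg = cfg, geno = geno, Y = Y, truth = sim$truth, eigen = eig,
       scans = scans)
}

## tiny genotype matrix straight from dosage values
tiny_geno <- function(dosages, chrom = 1, pos = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq(1e5, by = 1e5, length.out = m)
  geno_matrix(dosages,
              data.frame(id = paste0(chrom, ":", pos), chrom = chrom,
                         pos = pos, ref = "A", alt = "G",
                         stringsAsFactors = FALSE))
}

## vectorized simple-regression z-scores (t statistics) of y on each column
simple_z <- function(y, D) {
  n <- length(y)
  D <- scale(D)
  r <- drop(crossprod(D, scale(y))) / (n - 1)
  r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
}

## one fine-mapping region: LD-structured genotypes, one causal variant
sim_region <- function(seed, n = 800, m = 60, beta = 0.35, freq = 0.4,
                       founders = 30, switch_rate = 0.15) {
  cfg <- sim_config(
    n_individuals = n, n_chromosomes = 1, n_variants_per_chrom = m,
    n_founder_haplotypes = founders, switch_rate = switch_rate,
    mean_spacing_bp = 5000, traits = "y",
    Vg = matrix(0), Ve = matrix(1),
    qtl_spec = list(qtl_spec(1, 150000, beta, frequency_target = freq)),
    seed = seed)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  list(geno = geno, y = sim$phenotypes$y, causal = sim$truth$causal$id)
}
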