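test_that("genotype simulation is deterministic and respects bounds", {
  cfg <- sim_config(n_individuals = 150, n_chromosomes = 2,
                    n_variants_per_chrom = 80, seed = 7)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$variants, g2$variants)
  expect_true(all(g1$dosages %in% c(0, 1, 2)))
  for (p in split(g1$variants$pos, g1$variants$chrom)) {
    expect_true(all(diff(p) > 0))
  }
  maf <- pmin(g1$variants$af, 1 - g1$variants$af)
  expect_true(all(maf >= cfg$maf_floor))
})

test_that("no recombination with two founders forces complete LD", {
  cfg <- sim_config(n_individuals = 60, n_chromosomes = 1,
                    n_variants_per_chrom = 40, n_founder_haplotypes = 2,
                    switch_rate = 0, seed = 3)
  g <- simulate_genotypes(cfg)
  ld <- ld_matrix(g)
  expect_true(all(abs(ld$r2 - 1) < 1e-12, na.rm = TRUE))
})

test_that("LD vanishes between distant variants at high switch rate", {
  r2_far <- unlist(lapply(1:10, function(s) {
    cfg <- sim_config(n_individuals = 250, n_chromosomes = 1,
                      n_variants_per_chrom = 120, n_founder_haplotypes = 200,
                      switch_rate = 0.5, mean_spacing_bp = 25000, seed = s)
    g <- simulate_genotypes(cfg)
    ld <- ld_matrix(g)
    far <- abs(outer(ld$pos, ld$pos, `-`)) > 1e6
    pairs <- which(far & upper.tri(far), arr.ind = TRUE)
    pairs <- pairs[sample(nrow(pairs), 5), , drop = FALSE]
    ld$r2[pairs]
  }))
  expect_length(r2_far, 50)
  expect_lt(mean(r2_far, na.rm = TRUE), 0.05)
})

test_that("founder-panel LD produces distance-decaying blocks", {
  cfg <- sim_config(n_individuals = 600, n_chromosomes = 1,
                    n_variants_per_chrom = 200, n_founder_haplotypes = 60,
                    switch_rate = 0.05, mean_spacing_bp = 5000,
                    founder_ld_decay_bp = 100000, seed = 15)
  g <- simulate_genotypes(cfg)
  ld <- ld_matrix(g)
  gap <- abs(outer(ld$pos, ld$pos, `-`))
  ut <- upper.tri(gap)
  near <- ut & gap > 0 & gap <= 20000
  far <- ut & gap > 500000
  expect_gt(mean(ld$r2[near], na.rm = TRUE), 5 * mean(ld$r2[far], na.rm = TRUE))
  expect_gt(mean(ld$r2[near], na.rm = TRUE), 0.2)

  ## decay disabled: adjacent variants are (near) independent
  cfg0 <- cfg; cfg0 <- sim_config(n_individuals = 600, n_chromosomes = 1,
                                  n_variants_per_chrom = 200,
                                  n_founder_haplotypes = 60,
                                  switch_rate = 0.05, mean_spacing_bp = 5000,
                                  founder_ld_decay_bp = 0, seed = 15)
  ld0 <- ld_matrix(simulate_genotypes(cfg0))
  expect_lt(mean(ld0$r2[near], na.rm = TRUE), 0.1)
})

test_that("pure-noise phenotypes have unit variance and no structure", {
  cfg <- sim_config(n_individuals = 5000, n_chromosomes = 1,
                    n_variants_per_chrom = 60, traits = c("t1", "t2"),
                    Vg = matrix(0, 2, 2), Ve = diag(2), seed = 11)
  sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  expect_gt(var(sim$phenotypes$t1), 0.9)
  expect_lt(var(sim$phenotypes$t1), 1.1)
  expect_gt(var(sim$phenotypes$t2), 0.9)
  expect_lt(var(sim$phenotypes$t2), 1.1)
  expect_lt(abs(cor(sim$phenotypes$t1, sim$phenotypes$t2)), 0.05)
})

test_that("planted QTL effects are recovered by OLS and induce anticorrelation", {
  cfg <- sim_config(n_individuals = 5000, n_chromosomes = 1,
                    n_variants_per_chrom = 60, traits = c("t1", "t2"),
                    Vg = matrix(0, 2, 2), Ve = diag(2),
                    qtl_spec = list(qtl_spec(1, 200000, c(1, -1),
                                             frequency_target = 0.4)),
                    seed = 12)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  x <- drop(dosage_of(g, "1:200000"))
  f1 <- summary(lm(sim$phenotypes$t1 ~ x))$coefficients[2, ]
  f2 <- summary(lm(sim$phenotypes$t2 ~ x))$coefficients[2, ]
  expect_lt(abs(f1["Estimate"] - 1), 3 * f1["Std. Error"])
  expect_lt(abs(f2["Estimate"] + 1), 3 * f2["Std. Error"])
  ## genotype-driven effects on the two traits point in opposite directions
  expect_lt(cor(fitted(lm(sim$phenotypes$t1 ~ x)),
                fitted(lm(sim$phenotypes$t2 ~ x))), 0)
})

test_that("recessive penalty lowers homozygote phenotypes by its magnitude", {
  cfg <- sim_config(n_individuals = 4000, n_chromosomes = 1,
                    n_variants_per_chrom = 40, traits = "y",
                    Vg = matrix(0), Ve = matrix(1),
                    qtl_spec = list(qtl_spec(1, 100000, 0,
                                             recessive_penalty = -5,
                                             frequency_target = 0.5)),
                    seed = 13)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  x <- drop(dosage_of(g, "1:100000"))
  diff_mean <- mean(sim$phenotypes$y[x == 2]) - mean(sim$phenotypes$y[x == 1])
  expect_lt(abs(diff_mean + 5), 0.3)
})

test_that("missing QTL position raises a named error", {
  cfg <- sim_config(n_individuals = 50, n_chromosomes = 1,
                    n_variants_per_chrom = 30, traits = "y",
                    Vg = matrix(0.3), Ve = matrix(0.7),
                    qtl_spec = list(qtl_spec(1, 99999, 0.5)), seed = 5)
  g <- simulate_genotypes(cfg)
  g2 <- g[, setdiff(g$variants$id, "1:99999")]
  expect_error(simulate_phenotypes(g2, cfg), "99999")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(Vg = matrix(c(1, 2, 2, 1), 2),
                          traits = c("a", "b")), "semi-definite")
  expect_error(sim_config(n_founder_haplotypes = 0), "founder")
  expect_error(sim_config(maf_floor = 0.7), "maf_floor")
  expect_error(sim_config(traits = c("a", "b"), Vg = matrix(0.5)), "2x2")
  expect_error(sim_config(qtl_spec = list(qtl_spec(9, 100, c(0, 0))),
                          traits = c("a", "b")), "outside")
})

test_that("annotation rates behave as binomial draws", {
  g <- tiny_geno(matrix(rbinom(2 * 1e5, 2, 0.5), 2, 1e5))
  a0 <- simulate_annotations(g, coding_rate = 0, seed = 1)
  expect_identical(sum(a0$coding), 0L)
  a1 <- simulate_annotations(g, coding_rate = 1, seed = 1)
  expect_identical(sum(a1$coding), nrow(g$variants))
  a <- simulate_annotations(g, coding_rate = 0.0034, seed = 2)
  expect_lt(abs(sum(a$coding) - 340), 3 * sqrt(340 * 0.9966))
  expect_true(all(a$impact[a$coding] %in% c("MODERATE", "HIGH")))
  expect_true(all(a$impact[!a$coding] %in% c("MODIFIER", "LOW")))
  af <- simulate_annotations(g, coding_rate = 0, seed = 1,
                             force_coding = g$variants$id[1:3])
  expect_identical(sum(af$coding), 3L)
})

test_that("phenotype covariance matches genetic plus residual components", {
  Vg <- 0.4 * matrix(c(1, 0.6, 0.6, 1), 2)
  Ve <- 0.6 * diag(2)
  cfg <- sim_config(n_individuals = 5000, n_chromosomes = 1,
                    n_variants_per_chrom = 150, traits = c("a", "b"),
                    Vg = Vg, Ve = Ve, seed = 19)
  sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  S <- cov(as.matrix(sim$phenotypes[, c("a", "b")]))
  expect_true(all(abs(S - (Vg + Ve)) < 0.07))
  expect_equal(unname(sim$truth$Vg_realized), unname(Vg), tolerance = 1e-8)
})
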