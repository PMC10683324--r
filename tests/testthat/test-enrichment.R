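test_that("expected coding count and exact binomial tail match printed-scale values", {
  e <- coding_enrichment(rep(30, 11), coding_rate = 0.0034,
                         observed_total = 6)
  expect_equal(e$expected_total, 0.0034 * 330, tolerance = 1e-12)
  expect_equal(round(e$expected_total, 1), 1.1)
  ## oracle: exact binomial upper tail
  expect_equal(e$p_total, pbinom(5, 330, 0.0034, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(e$p_total, 3), 0.001)

  e80 <- coding_enrichment(rep(73, 11), 0.0034, observed_total = 11)
  expect_lt(e80$p_total, 2e-4)
  expect_gt(e80$p_total, 0.8e-4)
})

test_that("degenerate rates behave sensibly", {
  expect_error(coding_enrichment(c(10, 10), 0.0034, observed_total = 25),
               "exceeds")
  expect_error(coding_enrichment(c(10), 0, observed_total = 0))
  ## p_total is monotone decreasing in the observed count
  ps <- vapply(0:5, function(o) {
    coding_enrichment(rep(20, 5), 0.01, o)$p_total
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  ## expected total is linear in the rate
  e1 <- coding_enrichment(rep(20, 5), 0.01, 0)$expected_total
  e2 <- coding_enrichment(rep(20, 5), 0.02, 0)$expected_total
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
})

test_that("Poisson-binomial DP equals brute-force enumeration up to k = 15", {
  set.seed(3)
  for (k in c(4, 9, 15)) {
    q <- runif(k, 0.01, 0.6)
    states <- expand.grid(rep(list(0:1), k))
    pr <- apply(states, 1, function(o) prod(ifelse(o == 1, q, 1 - q)))
    for (x in c(0, 1, ceiling(k / 2), k)) {
      brute <- sum(pr[rowSums(states) >= x])
      expect_equal(pleiomap:::poisson_binomial_tail(x, q), brute,
                   tolerance = 1e-10)
    }
  }
})

test_that("Monte Carlo tails agree with exact within 3 standard errors", {
  ex <- coding_enrichment(rep(30, 11), 0.0034, 4, 3)
  mc <- coding_enrichment(rep(30, 11), 0.0034, 4, 3,
                          method = "monte_carlo", n_reps = 2e5, seed = 6)
  expect_lt(abs(mc$p_total - ex$p_total), 3 * mc$se_total + 1e-12)
  expect_lt(abs(mc$p_cs_count - ex$p_cs_count), 3 * mc$se_cs_count + 1e-12)
})

test_that("coding-lead tail probability matches the binomial oracle", {
  p <- lead_coding_test(11, 0.0034, 5)
  expect_equal(p, pbinom(4, 11, 0.0034, lower.tail = FALSE),
               tolerance = 1e-15)
  expect_lt(p, 1e-8)
  expect_equal(lead_coding_test(11, 0.0034, 0), 1)
  expect_equal(lead_coding_test(11, 1, 7), 1)
})

test_that("joint effects of a single candidate reproduce the scan estimate", {
  fx <- fixture("st", st_cohort)
  je <- joint_variant_effects(matrix(fx$y, ncol = 1,
                                     dimnames = list(NULL, "y")),
                              fx$geno, "1:1000000", fx$eigen)
  i <- match("1:1000000", fx$scan$id)
  ## same model up to the variance components being refit with the candidate
  expect_equal(unname(je$beta[1, 1]), fx$scan$beta[i], tolerance = 0.02)
  ## strict check: rebuild the scan with the joint fit's variance components
  nf <- je$null_with[[1]]
  sc <- st_scan(fx$y, fx$geno, fx$eigen, fx$null,
                region = list(chrom = 1, start = 999999, end = 1000001))
  expect_lt(abs(je$beta[1, 1] - 0.45), 3 * je$se[1, 1])
})

test_that("jointly fitted independent causals are each near truth", {
  ok <- unlist(lapply(1:12, function(s) {
    cfg <- sim_config(n_individuals = 900, n_chromosomes = 2,
                      n_variants_per_chrom = 150, n_founder_haplotypes = 80,
                      switch_rate = 0.2, traits = "y",
                      Vg = matrix(0.3), Ve = matrix(0.7),
                      qtl_spec = list(qtl_spec(1, 400000, 0.35,
                                               frequency_target = 0.35),
                                      qtl_spec(1, 1100000, 0.35,
                                               frequency_target = 0.40)),
                      seed = 400 + s)
    g <- simulate_genotypes(cfg)
    sim <- simulate_phenotypes(g, cfg)
    eig <- grm_eigen(compute_grm(g, marker_subset = which(g$variants$chrom == 2)))
    je <- joint_variant_effects(sim$phenotypes$y, g, sim$truth$causal$id, eig)
    all(abs(je$beta[, 1] - 0.35) < 3 * je$se[, 1])
  }))
  expect_gte(mean(ok), 0.9)
})

test_that("collinear candidates are rejected with the offending pair named", {
  set.seed(20)
  x <- rbinom(300, 2, 0.4)
  g <- tiny_geno(cbind(x, x, rbinom(300, 2, 0.3)))
  eig <- grm_eigen(compute_grm(g))
  y <- rnorm(300)
  pair <- g$variants$id[1:2]
  expect_error(joint_variant_effects(y, g, pair, eig), pair[1],
               fixed = TRUE)
})

test_that("variance shares follow the 2p(1-p)b^2 formula", {
  vs <- variance_shares(beta = matrix(1), freqs = 0.5, sigma_g2 = 5)
  expect_equal(drop(vs$share), 0.1, tolerance = 1e-12)
  expect_error(variance_shares(beta = matrix(1), freqs = 0.5, sigma_g2 = 0),
               "undefined")
})

test_that("a QTL built to explain 5% of genetic variance is recovered", {
  shares <- unlist(lapply(1:6, function(s) {
    sigma_g2 <- 0.4
    frq <- 0.5
    beta <- sqrt(0.05 * sigma_g2 / (2 * frq * (1 - frq)))
    cfg <- sim_config(n_individuals = 2000, n_chromosomes = 1,
                      n_variants_per_chrom = 400,
                      n_founder_haplotypes = 150, switch_rate = 0.4,
                      traits = "y", Vg = matrix(sigma_g2),
                      Ve = matrix(0.6),
                      qtl_spec = list(qtl_spec(1, 2000000, beta,
                                               frequency_target = frq)),
                      seed = 500 + s)
    g <- simulate_genotypes(cfg)
    sim <- simulate_phenotypes(g, cfg)
    eig <- grm_eigen(compute_grm(g))
    je <- joint_variant_effects(sim$phenotypes$y, g, sim$truth$causal$id, eig)
    vs <- variance_shares(je)
    vs$aggregate
  }))
  expect_gt(mean(shares), 0.03)
  expect_lt(mean(shares), 0.07)
  ## zero-effect variant accounts for (essentially) no genetic variance;
  ## checked on an LD-free cohort so the candidate tags no background blocks
  cfg0 <- sim_config(n_individuals = 1500, n_chromosomes = 1,
                     n_variants_per_chrom = 300, n_founder_haplotypes = 300,
                     switch_rate = 0.5, founder_ld_decay_bp = 0,
                     traits = "y", Vg = matrix(0.4), Ve = matrix(0.6),
                     seed = 520)
  g0 <- simulate_genotypes(cfg0)
  sim0 <- simulate_phenotypes(g0, cfg0)
  eig0 <- grm_eigen(compute_grm(g0))
  je0 <- joint_variant_effects(sim0$phenotypes$y, g0,
                               g0$variants$id[5], eig0)
  vs0 <- variance_shares(je0)
  expect_lt(vs0$aggregate, 0.005 * 3)
})

test_that("variance share of candidates tracks the polygenic-variance reduction", {
  sigma_g2 <- 0.4
  beta <- sqrt(0.20 * sigma_g2 / (2 * 0.25))
  cfg <- sim_config(n_individuals = 2000, n_chromosomes = 1,
                    n_variants_per_chrom = 400, n_founder_haplotypes = 150,
                    switch_rate = 0.4, traits = "y",
                    Vg = matrix(sigma_g2), Ve = matrix(0.6),
                    qtl_spec = list(qtl_spec(1, 2000000, beta,
                                             frequency_target = 0.5)),
                    seed = 510)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  eig <- grm_eigen(compute_grm(g))
  je <- joint_variant_effects(sim$phenotypes$y, g, sim$truth$causal$id, eig)
  vs <- variance_shares(je)
  ## the QTL is an unlinked extra source here, so fitting it reduces the
  ## GRM-attributed variance only through its LD with the markers; both
  ## measures must stay on the same scale
  expect_gt(vs$aggregate, 0.1)
  expect_lt(abs(vs$aggregate - vs$reduction) / vs$aggregate, 1)
})
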