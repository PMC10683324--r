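test_that("GRM matches the VanRaden formula on hand-computable cases", {
  g2 <- tiny_geno(cbind(c(0, 1, 2), c(0, 1, 2)))
  K <- compute_grm(g2)$K
  ## each marker: p = 0.5, W = (-1, 0, 1), denom = 2 * 2 * 0.25 = 1
  expect_equal(unname(K), matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3),
               tolerance = 1e-12)

  ## identical genotype rows give identical GRM rows
  set.seed(2)
  d <- matrix(rbinom(40 * 20, 2, 0.4), 40, 20)
  d[2, ] <- d[1, ]
  K2 <- compute_grm(tiny_geno(d))$K
  expect_equal(K2[1, ], K2[2, ], tolerance = 1e-12)

  expect_error(compute_grm(tiny_geno(matrix(2, 5, 3))), "monomorphic")
})

test_that("GRM off-diagonals center at zero for unrelated individuals", {
  set.seed(3)
  d <- matrix(rbinom(200 * 5000, 2, runif(5000, 0.1, 0.9)[col(matrix(0, 200, 5000))]),
              200, 5000)
  K <- compute_grm(tiny_geno(d))$K
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.02)
  expect_gt(mean(diag(K)), 0.8)
  expect_lt(mean(diag(K)), 1.5)
})

test_that("eigendecomposition reconstructs the GRM", {
  fx <- fixture("st", st_cohort)
  grm <- compute_grm(fx$geno)
  e <- grm_eigen(grm)
  K2 <- tcrossprod(sweep(e$vectors, 2, e$values, `*`), e$vectors)
  expect_lt(norm(K2 - grm$K, "F") / norm(grm$K, "F"), 1e-6)
})

test_that("null REML recovers heritability and detects its absence", {
  fx <- fixture("st", st_cohort)
  ## the fixture GRM uses chromosome-2 markers only, which tag roughly half
  ## of the genome-wide polygenic variance (simulated h2 = 0.3)
  expect_gt(fx$null$h2, 0.08)
  expect_lt(fx$null$h2, 0.45)
  ## permuted phenotypes destroy the genetic signal
  set.seed(5)
  nf0 <- fit_null(sample(fx$y), fx$eigen)
  expect_lt(nf0$h2, 0.05)
})

test_that("identity GRM gives the closed-form i.i.d. likelihood", {
  set.seed(6)
  n <- 400
  y <- rnorm(n, sd = 1.3)
  eig <- grm_eigen(diag(n))
  nf <- fit_null(y, eig)
  ## total variance equals the REML (n-1 denominator) variance
  expect_equal(nf$sigma_g2 + nf$sigma_e2, var(y), tolerance = 1e-6)
  s2 <- var(y)
  ll_closed <- -0.5 * ((n - 1) * (log(2 * pi * s2) + 1) + log(n))
  expect_equal(nf$loglik, ll_closed, tolerance = 1e-6)
})

test_that("scan degenerates to OLS when the polygenic variance is zero", {
  fx <- fixture("st", st_cohort)
  null0 <- fx$null
  null0$sigma_g2 <- 0
  null0$sigma_e2 <- 1
  sc <- st_scan(fx$y, fx$geno, fx$eigen, null0)
  j <- c(3, 57, 200)
  for (jj in j) {
    f <- summary(lm(fx$y ~ fx$geno$dosages[, jj]))$coefficients[2, ]
    expect_equal(sc$beta[jj], unname(f["Estimate"]), tolerance = 1e-8)
    expect_equal(sc$se[jj], unname(f["Std. Error"]), tolerance = 1e-8)
    expect_equal(sc$t[jj], unname(f["t value"]), tolerance = 1e-8)
  }
})

test_that("a variant conditioned on itself is reported collinear", {
  fx <- fixture("st", st_cohort)
  lead <- "1:1000000"
  covar <- dosage_of(fx$geno, lead)
  nf <- fit_null(fx$y, fx$eigen, covariates = covar)
  sc <- st_scan(fx$y, fx$geno, fx$eigen, nf, covariates = covar)
  i <- match(lead, sc$id)
  expect_identical(sc$reason[i], "collinear")
  expect_true(is.na(sc$p[i]))
})

test_that("planted QTL are detected with effects near truth", {
  fx <- fixture("st", st_cohort)
  sc <- fx$scan
  for (id in fx$truth$causal$id) {
    i <- match(id, sc$id)
    expect_lt(sc$p[i], 1.43e-8)
    expect_lt(abs(sc$beta[i] - 0.45), 3 * sc$se[i])
  }
})

test_that("multivariate EM-REML agrees with univariate REML when T = 1", {
  fx <- fixture("st", st_cohort)
  nf <- fx$null
  mv <- fit_null_mv(matrix(fx$y, ncol = 1), fx$eigen)
  expect_true(mv$converged)
  expect_lt(abs(drop(mv$Vg) - nf$sigma_g2), 1e-5)
  expect_lt(abs(drop(mv$Ve) - nf$sigma_e2), 1e-5)
  expect_lt(abs(mv$loglik - nf$loglik), 1e-5)
})

test_that("multivariate fit recovers genetic correlation", {
  rg <- unlist(lapply(1:4, function(s) {
    Vg <- 0.5 * matrix(c(1, 0.8, 0.8, 1), 2)
    cfg <- sim_config(n_individuals = 700, n_chromosomes = 2,
                      n_variants_per_chrom = 250, traits = c("a", "b"),
                      Vg = Vg, Ve = 0.5 * diag(2), seed = 100 + s)
    g <- simulate_genotypes(cfg)
    sim <- simulate_phenotypes(g, cfg)
    eig <- grm_eigen(compute_grm(g))
    mv <- fit_null_mv(as.matrix(sim$phenotypes[, c("a", "b")]), eig)
    mv$Vg[1, 2] / sqrt(mv$Vg[1, 1] * mv$Vg[2, 2])
  }))
  expect_true(all(rg > 0.6 & rg < 0.95))
})

test_that("independent traits give near-zero genetic covariance", {
  covs <- unlist(lapply(1:5, function(s) {
    cfg <- sim_config(n_individuals = 600, n_chromosomes = 1,
                      n_variants_per_chrom = 300, traits = c("a", "b"),
                      Vg = 0.4 * diag(2), Ve = 0.6 * diag(2), seed = 200 + s)
    g <- simulate_genotypes(cfg)
    sim <- simulate_phenotypes(g, cfg)
    eig <- grm_eigen(compute_grm(g))
    fit_null_mv(as.matrix(sim$phenotypes[, c("a", "b")]), eig)$Vg[1, 2]
  }))
  expect_lt(abs(mean(covs)), 0.1)
})

test_that("multi-trait scan matches the single-trait scan in the T = 1 limit", {
  fx <- fixture("st", st_cohort)
  mv1 <- fit_null_mv(matrix(fx$y, ncol = 1, dimnames = list(NULL, "y")),
                     fx$eigen)
  mt <- mt_scan(matrix(fx$y, ncol = 1, dimnames = list(NULL, "y")),
                fx$geno, fx$eigen, mv1)
  st <- fx$scan
  ok <- !is.na(st$p) & !is.na(mt$p) & st$p < 0.999
  rel <- abs(log10(st$p[ok]) - log10(mt$p[ok])) / pmax(-log10(st$p[ok]), 0.1)
  expect_lt(max(rel), 0.10)
  expect_equal(mt[["beta.y"]][ok], st$beta[ok], tolerance = 1e-6)
})

test_that("multi-trait scan gains power on a single-trait signal", {
  ## a variant affecting 1 of 6 correlated traits: the joint Wald test should
  ## reach the Bonferroni-equivalent single-trait significance in most
  ## replicates (the multivariate gain comes from the trait correlations)
  hits <- unlist(lapply(1:10, function(s) {
    T <- 6
    eff <- c(0.4, rep(0, T - 1))
    Re <- matrix(0.6, T, T); diag(Re) <- 1
    cfg <- sim_config(n_individuals = 700, n_chromosomes = 1,
                      n_variants_per_chrom = 150,
                      n_founder_haplotypes = 100, switch_rate = 0.3,
                      traits = paste0("t", 1:T),
                      Vg = 0.15 * Re, Ve = 0.85 * Re,
                      qtl_spec = list(qtl_spec(1, 500000, eff,
                                               frequency_target = 0.4)),
                      seed = 300 + s)
    g <- simulate_genotypes(cfg)
    sim <- simulate_phenotypes(g, cfg)
    eig <- grm_eigen(compute_grm(g))
    Y <- as.matrix(sim$phenotypes[, cfg$traits])
    mv <- fit_null_mv(Y, eig)
    mt <- mt_scan(Y, g, eig, mv,
                  region = list(chrom = 1, start = 490000, end = 510000))
    st1 <- st_scan(Y[, 1], g, eig, fit_null(Y[, 1], eig),
                   region = list(chrom = 1, start = 490000, end = 510000))
    i <- match("1:500000", mt$id)
    mt$p[i] <= min(st1$p[match("1:500000", st1$id)] * T, 1)
  }))
  expect_gte(mean(hits), 0.5)
})

test_that("multi-trait scan is calibrated under the null", {
  cfg <- sim_config(n_individuals = 800, n_chromosomes = 2,
                    n_variants_per_chrom = 500, n_founder_haplotypes = 200,
                    switch_rate = 0.5, traits = c("a", "b"),
                    Vg = 0.3 * diag(2), Ve = 0.7 * diag(2), seed = 77)
  g <- simulate_genotypes(cfg)
  eig <- grm_eigen(compute_grm(g))
  set.seed(78)
  ## phenotypes drawn from the exact null model (polygenic, no QTL)
  Y <- sapply(c(0.3, 0.3), function(sg) {
    eig$vectors %*% (sqrt(sg * eig$values + 0.7) * rnorm(800))
  })
  colnames(Y) <- c("a", "b")
  mv <- fit_null_mv(Y, eig)
  mt <- mt_scan(Y, g, eig, mv)
  expect_lt(abs(mean(mt$p < 0.05, na.rm = TRUE) - 0.05), 0.01)
})

test_that("missing phenotypes trigger listwise subsetting with re-decomposition", {
  fx <- fixture("st", st_cohort)
  y2 <- fx$y
  y2[1:100] <- NA
  nf <- fit_null(y2, fx$eigen)
  expect_identical(nf$n, length(fx$y) - 100L)
  sc <- st_scan(y2, fx$geno, fx$eigen, nf,
                region = list(chrom = 1, start = 900000, end = 1100000))
  expect_true(all(sc$n == length(fx$y) - 100L))
  i <- match("1:1000000", sc$id)
  expect_lt(sc$p[i], 1e-6)
})
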