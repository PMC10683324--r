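---
title: "Methods: mixed-model multi-trait fine-mapping in pleiomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model multi-trait fine-mapping in pleiomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiomap)
```

pleiomap implements a complete association and fine-mapping workflow for
cohorts of related individuals measured on many correlated quantitative
traits — the setting typical of livestock mapping populations, where a
handful of large-effect, often pleiotropic variants segregate against a
polygenic background. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic cohorts used in
the tests do and do not establish about real data.

## The association model

Single-trait scans fit, for each variant $i$,

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{x}_i\beta_i + \mathbf{g} + \mathbf{e},
\qquad \mathbf{g} \sim N(0, \sigma_g^2 \mathbf{G}), \quad
\mathbf{e} \sim N(0, \sigma_e^2 \mathbf{I}),$$

where $\mathbf{y}$ holds trait deviations (one record per individual;
repeated records should be pre-averaged), $\mathbf{x}_i$ the allele dosages
in $[0,2]$, and $\mathbf{G}$ the genomic relationship matrix computed with
VanRaden's first method from centered dosages
(`compute_grm()`): $\mathbf{G} = \mathbf{W}\mathbf{W}'/2\sum_k p_k(1-p_k)$.

Variance components are estimated **once under the null** (`fit_null()`, no
variant term) and held fixed for every per-variant Wald test. This is the
standard population-scale approximation: after rotating the model by the
eigenvectors of $\mathbf{G}$ the covariance is diagonal, REML reduces to a
one-dimensional optimization over $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$,
and each variant test becomes a weighted least-squares slope. It differs
from exact per-variant REML by a quantity that is negligible at the effect
sizes of interest, and it is orders of magnitude faster. P-values come from
a t distribution with $n - p - 1$ degrees of freedom rather than a normal,
which is slightly conservative at moderate $n$. When the estimated
$\sigma_g^2$ is zero the scan reduces algebraically to ordinary least
squares, and the test suite asserts that identity to $10^{-8}$.

Missing phenotypes are handled by listwise deletion followed by
re-decomposition of the kinship on the retained subset; phenotypes are never
imputed. Variants collinear with a covariate (including a conditioning
variant tested against itself) are reported missing with the reason code
`"collinear"`.

### Multivariate model

`fit_null_mv()` estimates trait-level genetic and residual covariance
matrices $(\mathbf{V}_g, \mathbf{V}_e)$ for up to 10 traits by EM on the
*restricted* likelihood. EM-REML rather than plain ML-EM matters: with an
intercept fitted, ML variance estimates are biased by a factor of roughly
$(n-1)/n$, which would break the exact agreement with the univariate REML
fit in the $T = 1$ limit (the suite checks agreement to $10^{-5}$). Each EM
iteration simultaneously diagonalizes $(\mathbf{V}_g, \mathbf{V}_e)$ via a
Cholesky-plus-eigen transform, so the $n$ per-individual $T \times T$
inversions collapse to elementwise weights and the fit takes seconds at
$n = 2000$. Convergence requires both a restricted log-likelihood change
below `tol_ll` (default $10^{-6}$) and a relative parameter change below
$10^{-8}$, within `max_iter` (default 500) iterations; $\mathbf{V}_e$ is
kept positive definite by flooring its eigenvalues at $10^{-6}$ of its
trace. `mt_scan()` then tests the $T$-vector of variant effects by
generalized least squares with the components fixed, comparing the Wald
statistic to $\chi^2_T$. Missing phenotypes are deleted listwise within a
trait group.

## Calibration of significance thresholds

`permutation_meff()` estimates the effective number of independent tests:
a simple-regression scan (intercept plus dosage, no covariates) is repeated
on permuted phenotypes, the best p-value of each scan is recorded, and the
Sidak relation $p_{corr} = 1 - (1-p)^{m_{eff}}$ is inverted pointwise. The
aggregation — the median of pointwise estimates over grid points whose
corrected p lies in $[0.01, 0.5]$ — is this package's choice, made because
the extreme tail of the permutation distribution is noisy at desk-scale
permutation counts; the pointwise coefficient of variation is reported as a
diagnostic. The estimate is clamped to $[1, m]$, which is what makes a
single-variant panel return exactly 1. The default of 10,000 permutations
balances stability against runtime; production analyses on large panels
typically use 100,000, available by argument. Permutations shuffle whole phenotype
vectors across individuals, preserving nothing but sample size — this
deliberately breaks the genetic structure, because the quantity being
calibrated is the null distribution of the *best* statistic across the
panel, not per-variant calibration.

`galwey_meff()` gives the effective number of independent traits from the
eigenvalues of the trait correlation matrix,
$m_{eff} = (\sum_k \sqrt{\lambda_k^+})^2 / \sum_k \lambda_k^+$; its integer
floor is the conventional Bonferroni divisor. `significance_threshold()`
then sets the family-wise threshold $\alpha/(m_{tests} \times m_{traits})$.
With $\alpha = 0.05$, 500,000 effective tests and 7 effective traits this
gives $1.43\times10^{-8}$ ($-\log_{10} = 7.84$); with 20,000 region-level
tests, $2.5\times10^{-6}$ ($-\log_{10} = 5.6$).

## QTL regions, credible sets, pleiotropy, conditional mapping

`call_qtl()` picks peaks greedily (most significant variant first,
absorbing significant neighbours within 1 Mb; p ties break to the lower
position). `build_qtlr()` merges QTL across traits by single-linkage
chaining of lead positions at 1 Mb — chaining was chosen over a hard
window because regions with two distant sub-peaks should remain one region;
as a result a region can span more than 1 Mb end to end. Within a region,
traits whose best p lies between the genome-wide threshold and $10^{-7}$
are recorded as *suggestive*. The 1 Mb rule is measured lead-to-lead, not
boundary-to-boundary.

Two kinds of credible sets are built. LD-based sets (`ld_credible_set()`)
take every variant with $r^2 \ge 0.90$ (or $0.80$) to the lead; thresholds
nest by construction. IBSS sets (`ibss_finemap()`) come from a
sum-of-single-effects regression fitted to summary statistics (z-scores and
the in-sample LD matrix) on the standardized scale with residual variance
fixed at 1. Each of up to `L = 10` effects carries a uniform prior over
variants; its prior effect variance is re-chosen every iteration by
maximizing the single-effect marginal likelihood over a 20-point log grid
on $[0.01, 1]$ (in units of the phenotypic variance), and the effect is
switched off when no positive value beats the null — this is what lets the
model report several credible sets only when several independent signals
exist. A 95% set is the smallest posterior-ordered collection of variants
reaching the coverage; sets whose minimum absolute pairwise dosage
correlation falls below 0.5 are discarded as impure (a conventional purity
cutoff). The algorithm only ever multiplies by the LD matrix, so
non-positive-definite LD needs no repair; a `ridge` argument exists for
callers who want one. With `L = 1` the posterior equals the closed-form
single-effect Bayes-factor enumeration exactly, which the suite checks to
$10^{-6}$.

Multi-trait sets (`mt_credible_set()`) follow a qualification-and-merge
rule: a trait group's multi-trait scan is used only when at least one of
its traits shows single-trait evidence at $p < 10^{-7}$ in the region; each
qualifying group contributes the LD set around its multi-trait lead
(smallest Wald p, ties to the lower position), and when both groups qualify
the union is reported as the merged set.

`pleiotropy_correlation()` quantifies signal sharing between two traits as
the Pearson correlation of t-values (primary) and of
$\mathrm{sign}(\hat\beta)\cdot(-\log_{10}p)$ (secondary) over variants
within 1 Mb of the lead, discarding variants non-significant
($p > 0.05$) in both traits. Fewer than 3 retained variants flags the
result unreliable rather than reporting a correlation.

`conditional_scan()` refits the regional scan with candidate variants as
fixed covariates inside a 10 Mb window; the null variance components are
re-estimated with the covariates in the model, which is cheap at region
scale and avoids attributing captured signal to the polygenic term.
`conditional_rounds()` iterates — new leads exceeding the round threshold
join the covariate list, each variant at most once — with default round
thresholds $2.5\times10^{-6}$ then $2\times10^{-5}$, both of which should
be re-derived for a new cohort from region-level effective test counts.

## Enrichment and variance accounting

`coding_enrichment()` tests whether credible sets contain more coding
(MODERATE/HIGH impact) variants than chance. The null model marks each set
member coding independently with the genome-wide coding proportion
(0.34% by default) — matching a null that draws from set sizes and the
global rate rather than repositioning sets on an annotated genome. The
total-count tail is an exact binomial on the summed set sizes; the
number-of-sets-with-a-coding-variant tail is an exact Poisson-binomial
computed by dynamic-programming convolution (checked against full $2^k$
enumeration up to $k = 15$); a Monte Carlo mode (default $10^6$
repetitions) simulates the same null and agrees within sampling error.
`lead_coding_test()` is the analogous binomial tail for coding *lead*
variants. On the published constants — 11 sets of ~30 members, rate
0.0034 — the machinery reproduces an expectation of 1.1 coding variants,
$p \approx 0.001$ for observing 6, $p \approx 1.3\times10^{-4}$ for 11
coding variants in sets averaging 73 members, and $p \approx 2\times10^{-10}$
for 5 coding leads of 11.

`joint_variant_effects()` fits all candidate variants simultaneously as
fixed effects (rejecting pairs with $r^2 \ge 0.99$), and
`variance_shares()` converts the joint effects to genetic-variance shares
$2p(1-p)\hat\beta^2/\hat\sigma_g^2$, using $\hat\sigma_g^2$ from the
*candidate-free* null fit, alongside the polygenic-variance reduction
$1 - \hat\sigma_g^2(\text{with})/\hat\sigma_g^2(\text{without})$. The two
measures agree only up to LD between candidates and the GRM markers; the
tests treat them as same-scale quantities, not as an identity.

## The synthetic cohort generator

Real mapping cohorts of this kind are not freely redistributable, so every
stage is exercised on cohorts from `simulate_genotypes()` /
`simulate_phenotypes()` / `simulate_annotations()` with known truth.

Genotypes are haplotype mosaics: each chromosome of each individual copies
a founder haplotype, switching founders with probability `switch_rate` per
variant, so identity-by-descent segments — and hence LD — decay with
distance. Founder alleles are thresholded from a latent AR(1) Gaussian
process along the chromosome (`founder_ld_decay_bp`, default 100 kb). The
latent process is the load-bearing design choice: with *independent*
founder columns, population LD is bounded by the realized founder-panel
correlation, of order $1/H$ for $H$ founders, so any panel large enough for
a smooth allele-frequency spectrum would produce essentially no block
structure. The copula construction keeps marginal frequencies exactly
U(0.05, 0.95) while giving the panel — and therefore the cohort —
distance-decaying LD blocks; setting the decay to 0 recovers independent
draws. Because alleles are *thresholded* latent variables, pairwise $r^2$
rarely reaches the values seen between literally co-inherited sequence
variants; simulated LD-based credible sets are therefore smaller than
sequence-level ones, and nothing in the test suite depends on large sets
arising naturally (tests that need specific $r^2$ values construct them).

Phenotypes follow $Y = \sum_q \mathbf{x}_q \boldsymbol\beta_q' +
\mathbf{g} + \mathbf{e}$. The polygenic term is a scaled sum over all
non-QTL variants — not a draw from an explicit GRM-covariance normal — so
that a GRM built from the same markers is internally consistent and
heritability recovery is a meaningful test; the realized sample covariance
of $\mathbf{g}$ is scaled to equal $\mathbf{V}_g$ exactly, while
$\mathbf{e}$ keeps its sampling noise. QTL act additively through raw
dosages, with an optional `recessive_penalty` added to every trait of
homozygous-alternate carriers — the device used to mimic recessive
deleterious alleles held at high frequency by a favourable additive effect.
Annotations flag each variant coding independently at `coding_rate`
(default 0.0034). Coordinates are 1-based inclusive, as in VCF; hard calls
in $\{0,1,2\}$ become fractional dosages by adding clipped Gaussian noise
(`dosage_noise_sd`) to exercise dosage-aware code paths. Everything is
reproducible from the single config seed.

`cattle_cohort_config()` packages the study-like conditions: eleven
conformation traits in a body-dimension block (6 traits) and a muscling
block (5), genetic correlations $+0.5$ within and $-0.25$ between blocks,
$h^2 = 0.35$, a pleiotropic QTL with opposite-signed effects on the two
blocks, a second QTL whose recessive penalty coexists with a favourable
additive muscling effect, and the 0.34% coding rate. No trait
heritabilities or covariance magnitudes are published for the motivating
cohort, so these are exposed as configuration, not hard-coded truths.

What passing tests on these cohorts shows: the estimators are calibrated
(null p-values uniform; credible-set coverage at or above nominal), recover
planted truth (heritability, effect sizes, variance shares) within stated
Monte-Carlo bounds, and the pipeline's decision rules behave as specified.
What they do not show: robustness to coalescent LD, population
stratification, selection, genotyping artefacts, or imputation error
beyond the bounded-noise model — none of which the generator emulates.

## Problem sizes and other choices

The shipped tests use desk-scale sizes chosen as the smallest at which the
checked properties are statistically decisive: null calibration at
$n = 2000$ individuals and 10,000 variants; parameter recovery at
$n = 2000$ with 40 phenotype replicates on a fixed genotype panel;
permutation calibration at 500 variants and 2000 permutations; credible-set
coverage over 100 single-causal regions; 20-replicate designs for the
pleiotropy and conditional-mapping decision rules. Tests of QTL detection
power place the planted QTL variance around 2–9% of the phenotypic
variance — large by human-genetics standards, deliberately so, mirroring
the major-gene architecture this kind of cohort is used to dissect.

Other numerical conventions: the HWE filter uses a 1-df chi-square on hard
calls obtained by rounding dosages (HWE screening belongs to the
array-genotype stage of such pipelines; an exact test would be a drop-in
replacement);
Mendelian inconsistencies are opposite homozygotes in declared
parent-offspring pairs; the individual genotyping-rate threshold removes
strictly-below-0.90 rates (a rate of exactly 0.90 is retained); BED
intervals are 0-based half-open and variant positions 1-based, so interval
$[s, e)$ covers positions $s{+}1..e$; post-imputation filters (MAF 0.02,
accuracy 0.80) apply only when accuracy metadata is present and are logged
as skipped otherwise; QC reports count per-filter failures, which may
overlap, alongside the exact removed/retained split.

## Known limitations

* Variance components fixed at null estimates make per-variant tests score-test-like; exact per-variant REML is out of scope.
* The IBSS fine-mapper assumes in-sample LD; out-of-sample LD panels are not supported.
* The generator's LD is mosaic/copula-based, not coalescent; allele-frequency and LD joint structure of real populations is only coarsely matched.
* X-chromosome dosage models, genotype imputation, phasing and pedigree reconstruction are out of scope.
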