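test_that("identical config and seed give identical cohorts", {
  cfg <- simulation_config(n_cases = 40, n_controls = 40, n_snps = 30,
                           n_blocks = 3, n_causal = 10, pop_multiplier = 10,
                           seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$panel$dosages, b$panel$dosages)
  expect_identical(a$sumstats, b$sumstats)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$env$sle_items, b$env$sle_items)
})

test_that("genotype panel respects block structure and frequencies", {
  cfg <- simulation_config(n_cases = 100, n_controls = 100, n_snps = 100,
                           n_blocks = 10, within_block_r = 0.8,
                           n_causal = 10, seed = 3)
  panel <- simulate_genotypes(cfg, n = 5000)
  meta <- panel$snp_meta
  expect_true(all(diff(meta$bp) > 0))
  # blocks span under the clumping window; gaps exceed it
  for (b in unique(meta$block)) {
    span <- diff(range(meta$bp[meta$block == b]))
    expect_lt(span, 300000)
  }
  gaps <- meta$bp[match(2:10, meta$block)] -
    meta$bp[match(2:10, meta$block) - 1]
  expect_true(all(gaps > 300000))
  # dosage values and allele-frequency conservation (3 binomial SE)
  expect_true(all(panel$dosages %in% 0:2))
  emp <- colMeans(panel$dosages) / 2
  se <- sqrt(meta$freq * (1 - meta$freq) / (2 * 5000))
  expect_true(all(abs(emp - meta$freq) < 3 * se + 1e-12))
  # mean adjacent within-block dosage r^2 near the calibrated target
  r2 <- vapply(which(diff(meta$block) == 0) + 1, function(j) {
    stats::cor(panel$dosages[, j - 1], panel$dosages[, j])^2
  }, numeric(1))
  expect_gt(mean(r2), 0.55)
  expect_lt(mean(r2), 0.75)
})

test_that("zero within-block correlation gives independent SNPs", {
  cfg <- simulation_config(n_cases = 50, n_controls = 50, n_snps = 20,
                           n_blocks = 2, within_block_r = 0, n_causal = 5,
                           seed = 11)
  panel <- simulate_genotypes(cfg, n = 4000)
  cors <- stats::cor(panel$dosages)
  diag(cors) <- 0
  expect_lt(max(abs(cors)), 0.08)
})

test_that("degenerate MAF range gives symmetric frequency", {
  cfg <- simulation_config(n_cases = 50, n_controls = 50, n_snps = 10,
                           n_blocks = 2, maf_range = c(0.5, 0.5),
                           n_causal = 2, seed = 7)
  panel <- simulate_genotypes(cfg, n = 5000)
  emp <- colMeans(panel$dosages) / 2
  expect_true(all(emp > 0.48 & emp < 0.52))
})

test_that("discovery noise model matches its stated standard error", {
  cfg <- simulation_config(n_cases = 10, n_controls = 10, n_snps = 3,
                           n_blocks = 1, n_causal = 1,
                           n_discovery = 15546, discovery_case_frac = 0.5,
                           seed = 2)
  meta <- data.frame(id = c("a", "b", "c"), chr = 1L, bp = c(1L, 2L, 3L),
                     a1 = "A", a2 = "G", freq = c(0.3, 0.3, 0.5))
  truth <- data.frame(id = meta$id, causal = TRUE, beta_std = 0,
                      true_log_or = c(0.2, 0, 0))
  ss <- simulate_discovery_sumstats(truth, meta, cfg)
  # plug-in oracle: balanced discovery => n_eff = n_discovery
  expect_equal(ss$se[1], 1 / sqrt(2 * 0.3 * 0.7 * 15546), tolerance = 1e-12)
  expect_equal(ss$log_or, log(ss$or), tolerance = 1e-12)
})

test_that("null discovery effects give uniform p-values", {
  cfg <- simulation_config(n_cases = 10, n_controls = 10, n_snps = 3000,
                           n_blocks = 300, n_causal = 1, seed = 4)
  m <- 3000
  meta <- data.frame(id = sprintf("s%04d", 1:m), chr = 1L, bp = 1:m,
                     a1 = "A", a2 = "G", freq = runif(m, 0.05, 0.5))
  truth <- data.frame(id = meta$id, causal = FALSE, beta_std = 0,
                      true_log_or = 0)
  ss <- simulate_discovery_sumstats(truth, meta, cfg)
  expect_gt(mean(ss$p < 0.05), 0.04)
  expect_lt(mean(ss$p < 0.05), 0.06)
})

test_that("a very large discovery study recovers the true effect", {
  cfg <- simulation_config(n_cases = 10, n_controls = 10, n_snps = 1,
                           n_blocks = 1, n_causal = 1,
                           n_discovery = 2e8, seed = 9)
  meta <- data.frame(id = "a", chr = 1L, bp = 1L, a1 = "A", a2 = "G",
                     freq = 0.3)
  truth <- data.frame(id = "a", causal = TRUE, beta_std = 1,
                      true_log_or = 0.2)
  ss <- simulate_discovery_sumstats(truth, meta, cfg)
  expect_lt(abs(ss$log_or - 0.2), 0.01)
})

test_that("exchangeable SLE items behave binomially and CTQ respects bounds", {
  cfg <- simulation_config(n_cases = 10, n_controls = 10, n_snps = 2,
                           n_blocks = 1, n_causal = 1,
                           sle_age_slope = 0, sle_sex_effect = 0,
                           sle_loading = 0, seed = 13)
  n <- 6000
  env <- simulate_environment(cfg, age = rep(45, n), sex = rep(0, n))
  p_items <- stats::plogis(seq(-2.6, -1.4, length.out = 12))
  mu <- sum(p_items)
  se <- sqrt(sum(p_items * (1 - p_items)) / n)
  expect_lt(abs(mean(env$sle_total) - mu), 2 * se)
  expect_true(all(env$sle_total == env$sle_dependent + env$sle_independent))
  expect_true(all(env$sle_total <= 12))
  expect_true(all(env$ctq_items %in% 1:5))
  expect_true(all(env$ctq_total >= 25 & env$ctq_total <= 125))
})

test_that("SLE count regression recovers the generative age slope", {
  cfg <- simulation_config(n_cases = 10, n_controls = 10, n_snps = 2,
                           n_blocks = 1, n_causal = 1, sle_loading = 0,
                           seed = 17)
  n <- 8000
  age <- sample(20:80, n, replace = TRUE)
  sex <- rbinom(n, 1, 0.5)
  env <- simulate_environment(cfg, age = age, sex = sex)
  fit <- stats::lm(env$sle_total ~ age + sex)
  # oracle slope: regress the model-implied expected count on age
  intercepts <- seq(-2.6, -1.4, length.out = 12)
  expected <- rowSums(stats::plogis(outer(rep(1, n), intercepts) +
    cfg$sle_age_slope * (age - 45) + cfg$sle_sex_effect * sex))
  oracle <- stats::coef(stats::lm(expected ~ age + sex))["age"]
  se <- summary(fit)$coefficients["age", "Std. Error"]
  expect_lt(abs(stats::coef(fit)["age"] - oracle), 2 * se)
  expect_lt(stats::coef(fit)["age"], 0)
})

test_that("phenotype model recovers generative odds ratios on a large cohort", {
  cfg <- simulation_config(n_cases = 6000, n_controls = 30000,
                           n_snps = 2, n_blocks = 1, n_causal = 1,
                           or_g = 1.22, or_e = 1.82, or_gxe = 1.28,
                           pop_multiplier = 2, seed = 19)
  n_pop <- 2 * 36000
  set.seed(101)
  z <- stats::rnorm(n_pop)
  e <- stats::rbinom(n_pop, 1, 0.45)
  ph <- simulate_phenotype(z, e, cfg)
  d <- data.frame(y = ph$case, z = z[ph$idx], e = e[ph$idx])
  fit <- stats::glm(y ~ z * e, binomial, data = d)
  co <- stats::coef(fit)
  # retrospective sampling preserves all log odds ratios but the intercept
  expect_lt(abs(co["z"] - log(1.22)), 0.05)
  expect_lt(abs(co["e"] - log(1.82)), 0.05)
  expect_lt(abs(co["z:e"] - log(1.28)), 0.05)
})

test_that("null generative model yields null PRS effect and no rGE", {
  cfg <- simulation_config(n_cases = 300, n_controls = 300, n_snps = 40,
                           n_blocks = 4, n_causal = 10, or_g = 1, or_e = 1,
                           or_gxe = 1, rge = 0, pop_multiplier = 8,
                           seed = 23)
  ch <- simulate_cohort(cfg)
  fit <- stats::glm(ch$phenotype$case ~ ch$z_true, binomial)
  co <- summary(fit)$coefficients
  expect_lt(abs(co[2, 1]), 2 * co[2, 2])
  ctrl <- ch$phenotype$case == 0
  r <- stats::cor(ch$z_true[ctrl], ch$env$sle_total[ctrl])
  expect_lt(abs(r), 2 / sqrt(sum(ctrl)))
})

test_that("configured rGE is induced between score and environment", {
  cfg <- simulation_config(n_cases = 400, n_controls = 400, n_snps = 40,
                           n_blocks = 4, n_causal = 10, or_g = 1, or_e = 1,
                           or_gxe = 1, rge = 0.4, pop_multiplier = 8,
                           sle_loading = 1, seed = 29)
  ch <- simulate_cohort(cfg)
  r <- stats::cor(ch$z_true, ch$env$sle_total)
  expect_gt(r, 0.1)
})
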