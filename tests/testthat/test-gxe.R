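test_that("logistic fit reproduces closed forms and a reference fit", {
  # balanced intercept-only
  y <- rep(0:1, each = 50)
  f <- fit_logistic(y, matrix(1, 100, 1, dimnames = list(NULL, "i")))
  expect_equal(unname(f$coef), 0, tolerance = 1e-8)
  expect_equal(f$loglik, 100 * log(0.5), tolerance = 1e-8)
  # 2x2 table (a,b,c,d) = (30,20,10,40): slope = log(ad/bc) = log(6)
  y2 <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  x2 <- c(rep(1, 50), rep(0, 50))
  f2 <- fit_logistic(y2, cbind(1, x = x2))
  expect_equal(unname(f2$coef["x"]), log(6), tolerance = 1e-7)
  # agreement with the standard glm on a random design
  set.seed(81)
  x <- cbind(1, a = rnorm(300), b = rnorm(300))
  y3 <- rbinom(300, 1, plogis(0.2 + 0.5 * x[, 2] - 0.3 * x[, 3]))
  f3 <- fit_logistic(y3, x)
  ref <- stats::glm(y3 ~ x[, 2] + x[, 3], binomial)
  expect_equal(unname(f3$coef), unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(unname(f3$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-6)
  expect_equal(f3$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
})

test_that("logistic fit is consistent and errors on degenerate designs", {
  set.seed(83)
  x <- rnorm(20000)
  y <- rbinom(20000, 1, plogis(0.5 * x))
  f <- fit_logistic(y, cbind(1, x = x))
  expect_gt(unname(f$coef["x"]), 0.45)
  expect_lt(unname(f$coef["x"]), 0.55)
  expect_error(fit_logistic(y, cbind(1, x = x, x2 = x)), "rank-deficient")
  expect_error(fit_logistic(rep(1, 10), matrix(1, 10, 1)), "constant")
  # perfect separation diverges
  ys <- rep(0:1, each = 20)
  xs <- c(rnorm(20, -8), rnorm(20, 8))
  expect_error(fit_logistic(ys, cbind(1, x = xs)), "separation")
})

test_that("Nagelkerke R2 matches direct evaluation and its bounds", {
  ll0 <- 100 * log(0.5)
  expect_equal(nagelkerke_r2(ll0, ll0, 100), 0)
  expect_equal(nagelkerke_r2(0, ll0, 100), 1)
  expect_equal(nagelkerke_r2(ll0 + 5, ll0, 100),
               nagelkerke_direct(ll0 + 5, ll0, 100), tolerance = 1e-12)
  expect_error(nagelkerke_r2(ll0 - 1, ll0, 100))
  expect_error(nagelkerke_r2(0, 0, 100), "degenerate")
})

test_that("variance attribution decomposes on the likelihood scale", {
  set.seed(85)
  n <- 400
  pcs <- matrix(rnorm(2 * n, sd = 0.05), n, 2,
                dimnames = list(NULL, c("PC1", "PC2")))
  prs <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.4 * prs + 2 * pcs[, 1]))
  x <- cbind("(Intercept)" = 1, PRS = prs, pcs)
  dr <- delta_r2_excluding_pcs(y, x, "PRS")
  expect_gte(dr$delta_r2, 0)
  expect_lte(dr$r2_full, 1)
  # loglik differences telescope exactly
  null_ll <- fit_logistic(y, x[, 1, drop = FALSE])$loglik
  expect_equal((dr$loglik_reduced - null_ll) +
                 (dr$loglik_full - dr$loglik_reduced),
               dr$loglik_full - null_ll, tolerance = 1e-10)
  expect_error(delta_r2_excluding_pcs(y, cbind(x, PRS2 = prs), "PRS"),
               "rank-deficient")
})

test_that("permutation p-values behave at the extremes and match asymptotics", {
  set.seed(87)
  n <- 100
  x <- cbind(1, g = rnorm(n))
  y <- rbinom(n, 1, 0.5)
  refit <- function(yp) {
    f <- fit_logistic(yp, x)
    f$coef["g"] / f$se["g"]
  }
  expect_equal(permutation_empirical_p(0, refit, y, B = 19, seed = 1), 1,
               tolerance = 0.11)
  expect_equal(permutation_empirical_p(1e6, refit, y, B = 19, seed = 1),
               1 / 20)
  # concordance with the asymptotic p on one null dataset
  f <- fit_logistic(y, x)
  z <- unname(f$coef["g"] / f$se["g"])
  p_asym <- 2 * pnorm(-abs(z))
  B <- 2000
  p_emp <- permutation_empirical_p(z, refit, y, B = B, seed = 2)
  expect_lt(abs(p_emp - p_asym), 2 * sqrt(p_asym * (1 - p_asym) / B) + 1 / B)
})

test_that("interaction tests carry their design and report coherent CIs", {
  set.seed(89)
  d <- draw_gxe_cohort(400, 400, or_gxe = 1.6)
  pcs <- matrix(rnorm(1600, sd = 0.03), 800, 2,
                dimnames = list(NULL, c("PC1", "PC2")))
  m <- test_multiplicative_interaction(d$y, d$g, d$e, pcs, B = 19, seed = 3)
  expect_s3_class(m, "gxe_fit_result")
  expect_equal(m$or, exp(m$estimate), tolerance = 1e-12)
  expect_equal(m$ci_lo, exp(m$estimate - qnorm(0.975) * m$se),
               tolerance = 1e-10)
  expect_gte(m$delta_r2, 0)
  expect_true(m$p_empirical > 0 && m$p_empirical <= 1)
  a <- test_additive_interaction(d$y, d$g, d$e, pcs, B = 19, seed = 3)
  expect_true(is.na(a$or))
  expect_gte(a$delta_r2, 0)
  # additive R2 increment is tiny under independence
  y0 <- sample(d$y)
  a0 <- test_additive_interaction(y0, d$g, d$e, pcs)
  expect_lt(a0$delta_r2, 0.005)
})

test_that("an OR-1.22 score explains about one percent of variance at study size", {
  set.seed(90)
  dr2 <- replicate(200, {
    d <- draw_gxe_cohort(1605, 1064, or_g = 1.22, or_e = 1, or_gxe = 1,
                         mult = 8)
    x <- cbind("(Intercept)" = 1, PRS = d$g)
    delta_r2_excluding_pcs(d$y, x, "PRS")$delta_r2
  })
  expect_gt(mean(dr2), 0.006)
  expect_lt(mean(dr2), 0.016)
})

test_that("an inverse generative interaction is estimated as protective", {
  set.seed(91)
  ests <- replicate(60, {
    d <- draw_gxe_cohort(240, 272, or_e = 2.27, or_gxe = 0.7, prev_e = 0.3)
    test_multiplicative_interaction(d$y, d$g, d$e)$estimate
  })
  expect_lt(mean(ests), 0)
  expect_lt(mean(exp(ests)), 1)
})

test_that("a purely multiplicative model departs from additivity", {
  set.seed(93)
  # case fraction well away from 1/2: near 50% the logistic surface is
  # locally linear and the additive-scale departure vanishes
  rej <- replicate(120, {
    d <- draw_gxe_cohort(200, 800, or_g = 2.0, or_e = 3.0, or_gxe = 1.0,
                         prev_e = 0.4)
    test_additive_interaction(d$y, d$g, d$e)$p_asymptotic < 0.05
  })
  expect_gt(mean(rej), 0.15)
})

test_that("gene-environment correlation is recovered within cases", {
  set.seed(95)
  coefs <- ses <- numeric(40)
  for (i in 1:40) {
    n <- 2000
    g <- rnorm(n)
    e <- 0.15 * g + rnorm(n)          # induced rGE
    y <- rbinom(n, 1, 0.4)
    r <- ge_correlation(e, g, case = y, subset = "cases")
    coefs[i] <- r$estimate; ses[i] <- r$se
  }
  mc_se <- sd(coefs) / sqrt(40)
  expect_lt(abs(mean(coefs) - 0.15), 2 * mc_se)
  # null in controls when injected nowhere
  set.seed(96)
  g <- rnorm(1000); e <- rnorm(1000); y <- rbinom(1000, 1, 0.5)
  r0 <- ge_correlation(e, g, case = y, subset = "controls")
  expect_gt(r0$p_asymptotic, 0.001)
  expect_error(ge_correlation(rep(1, 100), rnorm(100), case = rep(0:1, 50),
                              subset = "cases"), "constant")
})

test_that("Bonferroni thresholds divide the family-wise level", {
  expect_identical(bonferroni_threshold(0.05, 10), 0.005)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_identical(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(1.2, 10))
})

test_that("sensitivity exclusion filters cases by interview mood", {
  case <- c(rep(1, 6), rep(0, 4))
  bdi <- c(5, 15, 25, 35, 45, 55, 1, 2, 3, 4)
  got <- sensitivity_exclude_depressed(function(keep) keep, case, bdi,
                                       bdi_threshold = 29)
  expect_identical(sum(got & case == 1), 3L)
  expect_true(all(got[case == 0]))
  # threshold above every case: identical to the full analysis
  all_in <- sensitivity_exclude_depressed(function(keep) keep, case, bdi,
                                          bdi_threshold = 100)
  expect_true(all(all_in))
  expect_error(sensitivity_exclude_depressed(function(keep) keep, case, bdi,
                                             bdi_threshold = 1), "no cases")
})

test_that("recall-bias-driven rGE attenuates after excluding depressed cases", {
  cfg <- simulation_config(n_cases = 600, n_controls = 600, n_snps = 40,
                           n_blocks = 4, n_causal = 10, rge = 0,
                           or_g = 1.5, recall_bias = 0.9, sle_loading = 0.3,
                           pop_multiplier = 8, seed = 97)
  ch <- simulate_cohort(cfg)
  prs <- ch$z_true
  full <- ge_correlation(ch$env$sle_total, prs, case = ch$phenotype$case,
                         subset = "cases")
  reduced <- sensitivity_exclude_depressed(function(keep) {
    ge_correlation(ch$env$sle_total[keep], prs[keep],
                   case = ch$phenotype$case[keep], subset = "cases")
  }, ch$phenotype$case, ch$phenotype$bdi, bdi_threshold = 29)
  expect_gt(full$estimate, 0)
  expect_lt(reduced$estimate, full$estimate)
})

test_that("log-odds curves recover category-specific PRS slopes", {
  set.seed(99)
  n <- 3000
  cat3 <- factor(sample(c("none", "mild", "moderate_severe"), n, TRUE),
                 levels = c("none", "mild", "moderate_severe"))
  prs <- rnorm(n)
  slope <- c(none = 0.5, mild = 0, moderate_severe = -0.5)[as.character(cat3)]
  icpt <- c(none = -1.5, mild = 0, moderate_severe = 1)[as.character(cat3)]
  y <- rbinom(n, 1, plogis(icpt + slope * prs))
  cv <- fig_logodds_by_category(y, prs, cat3)
  sl <- vapply(split(cv, cv$category), function(d) {
    unname(coef(lm(logodds ~ prs, d))["prs"])
  }, numeric(1))
  expect_gt(sl[["none"]], 0.3)
  expect_lt(sl[["moderate_severe"]], -0.3)
})

test_that("the threshold grid emits one row per model, environment and p_T", {
  set.seed(103)
  n <- 400
  raw <- matrix(rnorm(n * 9), n, 9)
  grid <- threshold_grid()
  colnames(raw) <- paste0("pT_", grid)
  std <- scale(raw)
  scores <- structure(list(raw = raw, std = std, n_snps = rep(5L, 9),
                           grid = grid, empty_thresholds = numeric(0)),
                      class = "score_matrix")
  y <- rbinom(n, 1, 0.45)
  pcs <- matrix(rnorm(2 * n, sd = 0.05), n, 2,
                dimnames = list(NULL, c("PC1", "PC2")))
  envs <- list(sle = rpois(n, 2), ctq = rnorm(n, 40, 8))
  plan <- analysis_plan(B = 0, seed = 5)
  out <- run_threshold_grid(plan, scores, envs, pcs, y,
                            ct_category = cut(envs$ctq, c(-Inf, 35, 45, Inf),
                                              labels = c("none", "mild",
                                                         "moderate_severe")))
  tab <- table(out$results$model_tag)
  expect_equal(unname(tab["main_prs"]), 9L)
  expect_equal(unname(tab["multiplicative"]), 18L)
  expect_equal(unname(tab["additive"]), 18L)
  expect_equal(unname(tab["ge_correlation"]), 18L)
  expect_equal(unname(tab["main_env"]), 2L)
  expect_equal(out$bonferroni, 0.005)
  expect_false(is.null(out$curve_data))
  expect_true(all(c("category", "prs", "logodds") %in% names(out$curve_data)))
})
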