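#' Logistic regression by iteratively reweighted least squares
#'
#' Thin wrapper around the standard IRLS fit returning exactly what the
#' interaction models need: coefficients, standard errors from the observed
#' information, and the binomial log-likelihood. Errors on rank-deficient
#' designs (naming the redundant columns) and on diverging coefficients
#' (separation).
#'
#' @param y 0/1 outcome, non-constant.
#' @param x Design matrix including the intercept column.
#' @return list with `coef`, `se`, `loglik`, `n`, `fitted`.
#' @export
fit_logistic <- function(y, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(length(y) == nrow(x))
  if (length(unique(y)) < 2) stop("outcome is constant")
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient design; redundant column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(
    x, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 200)
  ))
  if (!fit$converged) stop("IRLS did not converge")
  co <- fit$coefficients
  # separation check on the per-SD scale so unit-norm columns (PCs) with
  # legitimately large raw coefficients do not trip it
  sdx <- apply(x, 2, stats::sd)
  scaled <- abs(co) * ifelse(sdx > 0, sdx, 1)
  if (any(scaled > 15)) {
    stop("apparent separation: coefficient diverging for column ",
         names(co)[which.max(scaled)])
  }
  p <- fit$rank
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- stats::setNames(numeric(p), colnames(x))
  se[fit$qr$pivot[seq_len(p)]] <- sqrt(diag(covmat))
  mu <- fit$fitted.values
  loglik <- sum(stats::dbinom(y, 1, mu, log = TRUE))
  list(coef = co, se = se, loglik = loglik, n = length(y), fitted = mu)
}

#' Ordinary least squares with coefficient inference
#'
#' @param y Numeric outcome.
#' @param x Design matrix including the intercept column.
#' @return list with `coef`, `se`, `p` (t-test), `r2` (multiple R-squared),
#'   `n`, `df_residual`.
#' @export
fit_ols <- function(y, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient design; redundant column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(x, y)
  res <- fit$residuals
  df <- length(y) - fit$rank
  sigma2 <- sum(res^2) / df
  p <- fit$rank
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]) * sigma2
  se <- stats::setNames(numeric(p), colnames(x))
  se[fit$qr$pivot[seq_len(p)]] <- sqrt(diag(covmat))
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  list(coef = fit$coefficients, se = se, p = pval, r2 = r2,
       n = length(y), df_residual = df)
}

#' Nagelkerke pseudo R-squared
#'
#' `R2 = (1 - exp(2 (ll_null - ll_full) / n)) / (1 - exp(2 ll_null / n))`:
#' the Cox-Snell likelihood-ratio R-squared rescaled by its maximum so a
#' perfectly predicting model reaches 1.
#'
#' @param loglik_full,loglik_null Log-likelihoods of the fitted and the
#'   intercept-only model (`loglik_full >= loglik_null`).
#' @param n Sample size.
#' @return R-squared in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_full, loglik_null, n) {
  stopifnot(n > 0, loglik_full >= loglik_null - 1e-8)
  if (loglik_null == 0) stop("degenerate null model with log-likelihood 0")
  cox_snell <- 1 - exp(2 * (loglik_null - loglik_full) / n)
  max_cs <- 1 - exp(2 * loglik_null / n)
  cox_snell / max_cs
}

#' Variance explained by a model term, excluding other covariates
#'
#' Nagelkerke R-squared of the full model minus that of the model without
#' the term of interest, both computed against the intercept-only null.
#' With principal components as the only other covariates this is the
#' conventional "variance explained excluding PCs".
#'
#' @param y 0/1 outcome.
#' @param x_full Full design matrix (with intercept).
#' @param term_cols Column names (or indices) of the term of interest.
#' @return list with `delta_r2`, `r2_full`, `r2_reduced`, `loglik_full`,
#'   `loglik_reduced`, `loglik_null`.
#' @export
delta_r2_excluding_pcs <- function(y, x_full, term_cols) {
  x_full <- as.matrix(x_full)
  if (is.character(term_cols)) term_cols <- match(term_cols, colnames(x_full))
  stopifnot(!anyNA(term_cols))
  full <- fit_logistic(y, x_full)
  reduced <- fit_logistic(y, x_full[, -term_cols, drop = FALSE])
  null <- fit_logistic(y, matrix(1, length(y), 1,
                                 dimnames = list(NULL, "(Intercept)")))
  n <- length(y)
  r2f <- nagelkerke_r2(full$loglik, null$loglik, n)
  r2r <- nagelkerke_r2(reduced$loglik, null$loglik, n)
  list(delta_r2 = r2f - r2r, r2_full = r2f, r2_reduced = r2r,
       loglik_full = full$loglik, loglik_reduced = reduced$loglik,
       loglik_null = null$loglik)
}

# Design matrix for the interaction models: intercept, main effects,
# PC x E and PC x PRS adjustment terms, and the PRS x E product last.
build_interaction_design <- function(prs, env, pcs = NULL) {
  n <- length(prs)
  stopifnot(length(env) == n)
  x <- cbind("(Intercept)" = 1, PRS = prs, E = env)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    stopifnot(nrow(pcs) == n)
    if (is.null(colnames(pcs))) colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    pce <- pcs * env
    colnames(pce) <- paste0(colnames(pcs), "_x_E")
    pcg <- pcs * prs
    colnames(pcg) <- paste0(colnames(pcs), "_x_PRS")
    x <- cbind(x, pcs, pce, pcg)
  }
  cbind(x, PRS_x_E = prs * env)
}

# Assemble one result row shared by all model fits.
gxe_fit_result <- function(model_tag, env_name, p_t, estimate, se, or,
                           loglik_full = NA_real_, loglik_reduced = NA_real_,
                           delta_r2, p_asymptotic, p_empirical = NA_real_,
                           n_used) {
  z <- stats::qnorm(0.975)
  out <- data.frame(
    model_tag = model_tag, env = env_name, p_t = p_t,
    estimate = estimate, se = se, or = or,
    ci_lo = if (is.na(or)) estimate - z * se else exp(log(or) - z * se),
    ci_hi = if (is.na(or)) estimate + z * se else exp(log(or) + z * se),
    loglik_full = loglik_full, loglik_reduced = loglik_reduced,
    delta_r2 = delta_r2, p_asymptotic = p_asymptotic,
    p_empirical = p_empirical, n_used = n_used,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gxe_fit_result", "data.frame")
  out
}

#' Permutation empirical p-value
#'
#' Permutes the outcome vector (breaking its link to all predictors while
#' preserving the predictor joint distribution), refits, and compares
#' absolute statistics: `p = (1 + #{|perm| >= |observed|}) / (B + 1)`.
#' Permutation refits that fail are discarded; more than 5% failures is an
#' error.
#'
#' @param observed_stat Observed test statistic.
#' @param refit Function taking a permuted outcome and returning the
#'   statistic.
#' @param y Outcome vector to permute.
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return Empirical p-value in `(0, 1]`.
#' @export
permutation_empirical_p <- function(observed_stat, refit, y, B, seed = 1L) {
  stopifnot(B >= 1)
  set.seed(seed)
  stat <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    stat[b] <- tryCatch(refit(sample(y)), error = function(e) NA_real_)
  }
  fails <- sum(is.na(stat))
  if (fails > 0.05 * B) {
    stop(fails, " of ", B, " permutation refits failed")
  }
  stat <- stat[!is.na(stat)]
  (1 + sum(abs(stat) >= abs(observed_stat))) / (length(stat) + 1)
}

#' Multiplicative PRS-by-environment interaction test
#'
#' Logistic regression of case status on the PRS × environment product,
#' co-varying for the main effects of PRS and environment, the principal
#' components, and the PC × environment and PC × PRS products. The
#' interaction's variance explained is the Nagelkerke R-squared difference
#' between the full model and the model omitting only the product term.
#'
#' @param y 0/1 case status.
#' @param prs Standardized polygenic score.
#' @param env Environment variable (adjusted SLE count or CTQ total).
#' @param pcs n × k PC matrix, or `NULL` to omit all PC terms.
#' @param B Permutations for the empirical p-value (0 skips it).
#' @param seed Seed for the permutations.
#' @param env_name,p_t Labels carried into the result row.
#' @return A `gxe_fit_result` row for the interaction term.
#' @export
test_multiplicative_interaction <- function(y, prs, env, pcs = NULL, B = 0,
                                            seed = 1L, env_name = "E",
                                            p_t = NA_real_) {
  x <- build_interaction_design(prs, env, pcs)
  fit <- fit_logistic(y, x)
  k <- "PRS_x_E"
  est <- fit$coef[k]; se <- fit$se[k]
  z <- est / se
  dr <- delta_r2_excluding_pcs(y, x, k)
  p_emp <- NA_real_
  if (B > 0) {
    refit <- function(yp) {
      f <- fit_logistic(yp, x)
      f$coef[k] / f$se[k]
    }
    p_emp <- permutation_empirical_p(z, refit, y, B, seed)
  }
  gxe_fit_result("multiplicative", env_name, p_t, unname(est), unname(se),
                 exp(unname(est)), dr$loglik_full, dr$loglik_reduced,
                 dr$delta_r2, 2 * stats::pnorm(-abs(z)), p_emp, length(y))
}

#' Additive PRS-by-environment interaction test
#'
#' Ordinary least squares of the 0/1 case status on the same design as the
#' multiplicative model; departure from additivity is carried by the
#' product-term coefficient on the linear-probability scale. Variance
#' explained is the multiple R-squared increment of the product term.
#'
#' @inheritParams test_multiplicative_interaction
#' @return A `gxe_fit_result` row (no odds ratio: linear scale).
#' @export
test_additive_interaction <- function(y, prs, env, pcs = NULL, B = 0,
                                      seed = 1L, env_name = "E",
                                      p_t = NA_real_) {
  x <- build_interaction_design(prs, env, pcs)
  k <- "PRS_x_E"
  full <- fit_ols(y, x)
  reduced <- fit_ols(y, x[, colnames(x) != k, drop = FALSE])
  tstat <- full$coef[k] / full$se[k]
  p_emp <- NA_real_
  if (B > 0) {
    refit <- function(yp) {
      f <- fit_ols(yp, x)
      f$coef[k] / f$se[k]
    }
    p_emp <- permutation_empirical_p(tstat, refit, y, B, seed)
  }
  gxe_fit_result("additive", env_name, p_t, unname(full$coef[k]),
                 unname(full$se[k]), NA_real_, NA_real_, NA_real_,
                 full$r2 - reduced$r2, unname(full$p[k]), p_emp, length(y))
}

#' Gene-environment correlation test
#'
#' Least-squares regression of the environment measure on the standardized
#' PRS, co-varying for principal components, within the requested subset
#' (cases, controls, or everyone). For the permutation p-value the PRS (and
#' PCs) rows are held fixed and the environment outcome is permuted within
#' the subset.
#'
#' @param env Environment measure (outcome).
#' @param prs Standardized polygenic score.
#' @param pcs PC matrix or `NULL`.
#' @param case 0/1 status, required unless `subset = "all"`.
#' @param subset `"cases"`, `"controls"` or `"all"`.
#' @inheritParams test_multiplicative_interaction
#' @return A `gxe_fit_result` row for the PRS coefficient.
#' @export
ge_correlation <- function(env, prs, pcs = NULL, case = NULL,
                           subset = c("cases", "controls", "all"),
                           B = 0, seed = 1L, env_name = "E",
                           p_t = NA_real_) {
  subset <- match.arg(subset)
  keep <- switch(subset,
    cases = case == 1, controls = case == 0,
    all = rep(TRUE, length(env)))
  stopifnot(any(keep))
  e <- env[keep]; g <- prs[keep]
  if (stats::var(e) == 0) stop("environment constant in subset ", subset)
  x <- cbind("(Intercept)" = 1, PRS = g)
  if (!is.null(pcs)) {
    p <- as.matrix(pcs)[keep, , drop = FALSE]
    if (is.null(colnames(p))) colnames(p) <- paste0("PC", seq_len(ncol(p)))
    x <- cbind(x, p)
  }
  fit <- fit_ols(e, x)
  tstat <- fit$coef["PRS"] / fit$se["PRS"]
  p_emp <- NA_real_
  if (B > 0) {
    refit <- function(ep) {
      f <- fit_ols(ep, x)
      f$coef["PRS"] / f$se["PRS"]
    }
    p_emp <- permutation_empirical_p(tstat, refit, e, B, seed)
  }
  res <- gxe_fit_result("ge_correlation", env_name, p_t,
                        unname(fit$coef["PRS"]), unname(fit$se["PRS"]),
                        NA_real_, NA_real_, NA_real_, NA_real_,
                        unname(fit$p["PRS"]), p_emp, sum(keep))
  res$subset <- subset
  res
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha Family-wise error rate in `(0, 1)`.
#' @param m Number of independent tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Sensitivity analysis excluding severely depressed cases
#'
#' Re-runs an analysis on the subset retaining all controls and only the
#' cases whose interview mood score falls below a severity threshold,
#' guarding against recall bias from low mood at interview.
#'
#' @param analysis Function of one argument: a logical keep-vector; should
#'   re-run the analysis on that subset and return its result.
#' @param case 0/1 status.
#' @param bdi Interview mood score; must be available for cases.
#' @param bdi_threshold Severity cut-off (cases with `bdi >= threshold` are
#'   excluded); default 29, the conventional severe band.
#' @return Whatever `analysis` returns, computed on the filtered subset.
#' @export
sensitivity_exclude_depressed <- function(analysis, case, bdi,
                                          bdi_threshold = 29) {
  stopifnot(length(case) == length(bdi))
  if (any(case == 1 & is.na(bdi))) stop("BDI missing for some cases")
  keep <- case == 0 | bdi < bdi_threshold
  if (!any(keep & case == 1)) stop("no cases remain below the BDI threshold")
  analysis(keep)
}

#' Analysis plan for the threshold grid
#'
#' @param models Model tags to fit.
#' @param grid P-value threshold grid (matching the score matrix).
#' @param B Permutations per fit (0 disables empirical p-values).
#' @param alpha Family-wise error rate.
#' @param m Bonferroni divisor; default 10, the number of planned tests.
#' @param seed Base seed for permutations.
#' @return An `analysis_plan` list.
#' @export
analysis_plan <- function(models = c("main_prs", "main_env", "multiplicative",
                                     "additive", "ge_correlation"),
                          grid = threshold_grid(), B = 0, alpha = 0.05,
                          m = 10, seed = 1L) {
  stopifnot(m >= 1, B >= 0, alpha > 0, alpha < 1)
  structure(list(models = models, grid = grid, B = as.integer(B),
                 alpha = alpha, m = as.integer(m), seed = as.integer(seed)),
            class = "analysis_plan")
}

#' Fit every planned model at every p-value threshold
#'
#' Produces one result row per (model, environment, threshold): PRS main
#' effects (variance explained excluding PCs), environment main effects,
#' multiplicative and additive interactions, and gene-environment
#' correlations within cases. Also emits the bar-chart table behind the
#' variance-explained-by-threshold figures (with significance stars at the
#' Bonferroni threshold) and, when a trauma category is supplied, predicted
#' log-odds curves of depression over the standardized PRS per category.
#'
#' @param plan An [analysis_plan()].
#' @param scores A `score_matrix` whose grid matches the plan's.
#' @param envs Named list of numeric environment vectors.
#' @param pcs PC matrix or `NULL`.
#' @param y 0/1 case status.
#' @param ct_category Optional factor for the per-category log-odds curves;
#'   drawn at the threshold whose multiplicative interaction (first
#'   environment) has the smallest asymptotic p.
#' @return list with `results` (data.frame), `bar_data`, `curve_data`,
#'   `bonferroni` (the per-test threshold used for stars).
#' @export
run_threshold_grid <- function(plan, scores, envs, pcs, y,
                               ct_category = NULL) {
  stopifnot(inherits(plan, "analysis_plan"), inherits(scores, "score_matrix"),
            identical(plan$grid, scores$grid), is.list(envs),
            !is.null(names(envs)))
  rows <- list()
  bonf <- bonferroni_threshold(plan$alpha, plan$m)
  seed_i <- plan$seed
  for (k in seq_along(plan$grid)) {
    p_t <- plan$grid[k]
    prs <- scores$std[, k]
    if ("main_prs" %in% plan$models) {
      x <- cbind("(Intercept)" = 1, PRS = prs,
                 if (!is.null(pcs)) as.matrix(pcs))
      fit <- fit_logistic(y, x)
      dr <- delta_r2_excluding_pcs(y, x, "PRS")
      z <- fit$coef["PRS"] / fit$se["PRS"]
      p_emp <- NA_real_
      if (plan$B > 0) {
        refit <- function(yp) {
          f <- fit_logistic(yp, x); f$coef["PRS"] / f$se["PRS"]
        }
        p_emp <- permutation_empirical_p(z, refit, y, plan$B,
                                         seed = seed_i <- seed_i + 1L)
      }
      rows[[length(rows) + 1L]] <- gxe_fit_result(
        "main_prs", NA_character_, p_t, unname(fit$coef["PRS"]),
        unname(fit$se["PRS"]), exp(unname(fit$coef["PRS"])),
        dr$loglik_full, dr$loglik_reduced, dr$delta_r2,
        2 * stats::pnorm(-abs(z)), p_emp, length(y))
    }
    for (ev in names(envs)) {
      e <- envs[[ev]]
      if ("multiplicative" %in% plan$models) {
        rows[[length(rows) + 1L]] <- test_multiplicative_interaction(
          y, prs, e, pcs, B = plan$B, seed = seed_i <- seed_i + 1L,
          env_name = ev, p_t = p_t)
      }
      if ("additive" %in% plan$models) {
        rows[[length(rows) + 1L]] <- test_additive_interaction(
          y, prs, e, pcs, B = plan$B, seed = seed_i <- seed_i + 1L,
          env_name = ev, p_t = p_t)
      }
      if ("ge_correlation" %in% plan$models) {
        rows[[length(rows) + 1L]] <- ge_correlation(
          e, prs, pcs, case = y, subset = "cases", B = plan$B,
          seed = seed_i <- seed_i + 1L, env_name = ev, p_t = p_t)
      }
    }
  }
  if ("main_env" %in% plan$models) {
    for (ev in names(envs)) {
      e <- envs[[ev]]
      x <- cbind("(Intercept)" = 1, E = e,
                 if (!is.null(pcs)) as.matrix(pcs))
      fit <- fit_logistic(y, x)
      dr <- delta_r2_excluding_pcs(y, x, "E")
      z <- fit$coef["E"] / fit$se["E"]
      p_emp <- NA_real_
      if (plan$B > 0) {
        refit <- function(yp) {
          f <- fit_logistic(yp, x); f$coef["E"] / f$se["E"]
        }
        p_emp <- permutation_empirical_p(z, refit, y, plan$B,
                                         seed = seed_i <- seed_i + 1L)
      }
      rows[[length(rows) + 1L]] <- gxe_fit_result(
        "main_env", ev, NA_real_, unname(fit$coef["E"]),
        unname(fit$se["E"]), exp(unname(fit$coef["E"])),
        dr$loglik_full, dr$loglik_reduced, dr$delta_r2,
        2 * stats::pnorm(-abs(z)), p_emp, length(y))
    }
  }
  results <- do.call(rbind, lapply(rows, function(r) {
    r$subset <- if (is.null(r$subset)) NA_character_ else r$subset
    r
  }))
  rownames(results) <- NULL
  bar <- results[results$model_tag %in% c("main_prs", "multiplicative") &
                   !is.na(results$p_t),
                 c("model_tag", "env", "p_t", "delta_r2", "p_asymptotic")]
  bar$significant <- !is.na(bar$p_asymptotic) & bar$p_asymptotic < bonf
  curve <- NULL
  if (!is.null(ct_category)) {
    mult <- results[results$model_tag == "multiplicative" &
                      results$env == names(envs)[1], ]
    best_k <- which(plan$grid == mult$p_t[which.min(mult$p_asymptotic)])
    curve <- fig_logodds_by_category(y, scores$std[, best_k], ct_category,
                                     pcs)
    attr(curve, "p_t") <- plan$grid[best_k]
  }
  list(results = results, bar_data = bar, curve_data = curve,
       bonferroni = bonf)
}

#' Predicted log-odds of disease by PRS within exposure categories
#'
#' Fits a logistic model of case status on the standardized PRS, the
#' exposure category, their interaction, and PCs, then evaluates the
#' predicted log odds on a PRS grid for each category (PCs at their means).
#'
#' @param y 0/1 case status.
#' @param prs Standardized PRS.
#' @param category Factor of exposure categories.
#' @param pcs PC matrix or `NULL`.
#' @param prs_grid PRS values to evaluate.
#' @return data.frame with `category`, `prs`, `logodds`.
#' @export
fig_logodds_by_category <- function(y, prs, category, pcs = NULL,
                                    prs_grid = seq(-3, 3, by = 0.1)) {
  category <- droplevels(as.factor(category))
  lv <- levels(category)
  dmy <- stats::model.matrix(~ category)[, -1, drop = FALSE]
  x <- cbind("(Intercept)" = 1, PRS = prs, dmy, dmy * prs)
  colnames(x) <- c("(Intercept)", "PRS", paste0("cat_", lv[-1]),
                   paste0("PRS_x_", lv[-1]))
  if (!is.null(pcs)) x <- cbind(x, as.matrix(pcs))
  fit <- fit_logistic(y, x)
  pc_part <- if (!is.null(pcs)) {
    sum(colMeans(as.matrix(pcs)) * fit$coef[colnames(as.matrix(pcs))])
  } else 0
  out <- do.call(rbind, lapply(seq_along(lv), function(i) {
    slope <- fit$coef["PRS"] +
      if (i > 1) fit$coef[paste0("PRS_x_", lv[i])] else 0
    icpt <- fit$coef["(Intercept)"] +
      if (i > 1) fit$coef[paste0("cat_", lv[i])] else 0
    data.frame(category = lv[i], prs = prs_grid,
               logodds = icpt + pc_part + slope * prs_grid,
               stringsAsFactors = FALSE)
  }))
  out
}
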