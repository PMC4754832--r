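#' Power-analysis scenario for a PRS-by-environment interaction
#'
#' @param n_cases,n_controls Retrospective sampling quotas.
#' @param or_g Odds ratio per SD of the standardized genetic score.
#' @param or_e Environment main-effect odds ratio.
#' @param or_gxe Interaction odds ratio under the alternative.
#' @param env_kind `"binary"` (exposure with a given prevalence) or
#'   `"count"` (sum of 12 exchangeable binary items).
#' @param env_prevalence Exposure prevalence for binary environments.
#' @param env_mean Mean count for count environments.
#' @param alpha Test level.
#' @param n_reps Simulation replicates (>= 100 for reported estimates).
#' @param baseline_logodds Disease-model intercept; default implies 10%
#'   prevalence at zero exposures.
#' @param pop_multiplier Source population size multiple for retrospective
#'   sampling.
#' @param seed Integer seed.
#' @return A `power_scenario` list.
#' @export
power_scenario <- function(n_cases, n_controls, or_g = 1.22, or_e = 1.82,
                           or_gxe = 1.28,
                           env_kind = c("binary", "count"),
                           env_prevalence = 0.45, env_mean = 1.8,
                           alpha = 0.05, n_reps = 1000L,
                           baseline_logodds = stats::qlogis(0.10),
                           pop_multiplier = 20, seed = 1L) {
  env_kind <- match.arg(env_kind)
  stopifnot(n_cases >= 1, n_controls >= 1, or_g > 0, or_e > 0, or_gxe > 0,
            alpha > 0, alpha < 1, n_reps >= 1,
            env_prevalence > 0, env_prevalence < 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 or_g = or_g, or_e = or_e, or_gxe = or_gxe,
                 env_kind = env_kind, env_prevalence = env_prevalence,
                 env_mean = env_mean, alpha = alpha,
                 n_reps = as.integer(n_reps),
                 baseline_logodds = baseline_logodds,
                 pop_multiplier = pop_multiplier, seed = as.integer(seed)),
            class = "power_scenario")
}

# One simulated case-control draw under the scenario's disease model.
simulate_gxe_draw <- function(s) {
  n_pop <- ceiling(s$pop_multiplier * (s$n_cases + s$n_controls))
  g <- stats::rnorm(n_pop)
  e <- switch(s$env_kind,
    binary = stats::rbinom(n_pop, 1L, s$env_prevalence),
    count = stats::rbinom(n_pop, 12L, s$env_mean / 12)
  )
  eta <- s$baseline_logodds + log(s$or_g) * g + log(s$or_e) * e +
    log(s$or_gxe) * g * e
  y <- stats::rbinom(n_pop, 1L, stats::plogis(eta))
  cases <- which(y == 1L); ctrls <- which(y == 0L)
  if (length(cases) < s$n_cases || length(ctrls) < s$n_controls) {
    stop(sprintf("quota unreachable: %d cases, %d controls drawn",
                 length(cases), length(ctrls)))
  }
  idx <- c(sample(cases, s$n_cases), sample(ctrls, s$n_controls))
  list(y = rep(c(1L, 0L), c(s$n_cases, s$n_controls)),
       g = g[idx], e = e[idx])
}

#' Simulation-based power of the multiplicative interaction test
#'
#' Per replicate: draw a standardized genetic score and an environment from
#' the scenario, assign case status from the logistic disease model, sample
#' retrospectively to the case/control quotas, fit the multiplicative
#' interaction model (no PCs: the power design has no stratification) and
#' record rejection of the interaction Wald test at `alpha`. Power is the
#' rejection fraction; its Monte-Carlo standard error is
#' `sqrt(p (1 - p) / n_reps)`. Replicates with separation are discarded and
#' counted; more than 5% is an error.
#'
#' @param s A [power_scenario()].
#' @return list with `power`, `mc_se`, `n_reps_used`, `n_failed`, `alpha`.
#' @export
estimate_power <- function(s) {
  stopifnot(inherits(s, "power_scenario"))
  set.seed(s$seed)
  reject <- rep(NA, s$n_reps)
  for (r in seq_len(s$n_reps)) {
    reject[r] <- tryCatch({
      d <- simulate_gxe_draw(s)
      x <- cbind("(Intercept)" = 1, G = d$g, E = d$e, GxE = d$g * d$e)
      fit <- fit_logistic(d$y, x)
      z <- fit$coef["GxE"] / fit$se["GxE"]
      2 * stats::pnorm(-abs(z)) < s$alpha
    }, error = function(e) NA)
  }
  n_failed <- sum(is.na(reject))
  if (n_failed > 0.05 * s$n_reps) {
    stop(n_failed, " of ", s$n_reps, " replicates failed")
  }
  reject <- reject[!is.na(reject)]
  p_hat <- mean(reject)
  list(power = p_hat,
       mc_se = sqrt(p_hat * (1 - p_hat) / length(reject)),
       n_reps_used = length(reject), n_failed = n_failed,
       alpha = s$alpha)
}
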