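#' Simulation configuration for a synthetic case-control G×E cohort
#'
#' Bundles every parameter of the synthetic-data generator: genotype panel
#' structure (block LD, allele frequencies), genetic architecture, discovery
#' GWAS noise, environment measures (12 stressful-life-event items, 25
#' childhood-trauma items), the disease model, and sampling.
#'
#' The defaults describe the study conditions the package is validated
#' against: 1605 cases and 1064 controls, discovery meta-analysis of
#' 7615 cases and 7931 controls, a per-SD polygenic-score odds ratio of 1.22
#' and an environment odds ratio of 1.82 for reporting two or more adult
#' stressful life events (2.27 is the corresponding literature value for
#' moderate/severe childhood trauma).
#'
#' @param n_cases,n_controls Validation cohort quotas after retrospective
#'   sampling.
#' @param n_snps Number of SNPs in the genotype panel.
#' @param n_blocks Number of contiguous LD blocks; if `n_snps` is not a
#'   multiple, the last block is smaller.
#' @param within_block_r Target dosage correlation between adjacent SNPs
#'   within a block, in `[0, 1)`. The latent-Gaussian correlation is
#'   calibrated so that the realized dosage correlation matches this value
#'   (up to attenuation when allele frequencies make it unreachable).
#' @param maf_range Length-2 interval in `(0, 0.5]` from which per-SNP A1
#'   allele frequencies are drawn uniformly. Frequencies are sorted within
#'   each block so that adjacent SNPs have comparable frequencies, as LD
#'   partners do.
#' @param n_causal Number of SNPs with nonzero true effects.
#' @param h2_liability Variance of the standardized-genotype effect sizes is
#'   `h2_liability / n_causal`; controls the magnitude of true discovery
#'   log odds ratios.
#' @param n_discovery Total discovery GWAS sample size used for the
#'   summary-statistic noise model.
#' @param discovery_case_frac Fraction of the discovery sample that are cases.
#' @param or_g Odds ratio per SD of the true polygenic liability score.
#' @param or_e Odds ratio per unit of the phenotype-model environment
#'   variable (see `env_kind`).
#' @param or_gxe Interaction odds ratio per (SD × environment unit).
#' @param rge Gene-environment correlation on the latent scale, in `[-1, 1]`.
#' @param baseline_logodds Intercept of the disease model; the implied
#'   population prevalence at zero exposures is `plogis(baseline_logodds)`.
#' @param pop_multiplier Source population size as a multiple of
#'   `n_cases + n_controls` for retrospective sampling.
#' @param env_kind Environment variable entering the disease model:
#'   `"sle2plus"` (indicator of two or more stressful life events, the
#'   default), `"sle_count"` (raw count), or `"ctq_total"` (standardized
#'   childhood-trauma total).
#' @param sle_age_slope Per-year change in each SLE item's log odds
#'   (negative: younger individuals report more events).
#' @param sle_sex_effect Log-odds increment for females on each SLE item.
#' @param sle_loading Loading of the shared per-person stress liability on
#'   each SLE item's log odds (0 makes items conditionally independent).
#' @param recall_bias Strength of reporting inflation of SLE items in cases
#'   with high interview mood scores; 0 disables it.
#' @param seed Integer seed; identical config and seed give identical output.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_cases = 1605L, n_controls = 1064L,
                              n_snps = 400L, n_blocks = 40L,
                              within_block_r = 0.8,
                              maf_range = c(0.05, 0.5),
                              n_causal = 100L, h2_liability = 0.3,
                              n_discovery = 15546L,
                              discovery_case_frac = 7615 / 15546,
                              or_g = 1.22, or_e = 1.82, or_gxe = 1.0,
                              rge = 0, baseline_logodds = stats::qlogis(0.10),
                              pop_multiplier = 20,
                              env_kind = c("sle2plus", "sle_count", "ctq_total"),
                              sle_age_slope = -0.02, sle_sex_effect = 0.25,
                              sle_loading = 0.8, recall_bias = 0,
                              seed = 1L) {
  env_kind <- match.arg(env_kind)
  stopifnot(
    n_cases >= 1, n_controls >= 1, n_snps >= 1, n_blocks >= 1,
    within_block_r >= 0, within_block_r < 1,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    n_causal >= 1, n_causal <= n_snps,
    h2_liability > 0, h2_liability < 1,
    n_discovery > 0, discovery_case_frac > 0, discovery_case_frac < 1,
    or_g > 0, or_e > 0, or_gxe > 0,
    rge >= -1, rge <= 1, pop_multiplier >= 2
  )
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_snps = as.integer(n_snps), n_blocks = as.integer(n_blocks),
    within_block_r = within_block_r, maf_range = maf_range,
    n_causal = as.integer(n_causal), h2_liability = h2_liability,
    n_discovery = as.integer(n_discovery),
    discovery_case_frac = discovery_case_frac,
    or_g = or_g, or_e = or_e, or_gxe = or_gxe, rge = rge,
    baseline_logodds = baseline_logodds, pop_multiplier = pop_multiplier,
    env_kind = env_kind, sle_age_slope = sle_age_slope,
    sle_sex_effect = sle_sex_effect, sle_loading = sle_loading,
    recall_bias = recall_bias, seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

# P(Z1 < t1, Z2 < t2) for standard bivariate normal with correlation rho.
bivariate_normal_cdf <- function(t1, t2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(t1) * stats::pnorm(t2))
  stats::integrate(
    function(z) stats::pnorm((t2 - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z),
    -Inf, t1, rel.tol = 1e-9
  )$value
}

# Correlation between threshold indicators I(Z1 < qnorm(p1)), I(Z2 < qnorm(p2)).
threshold_indicator_cor <- function(p1, p2, rho) {
  t1 <- stats::qnorm(p1); t2 <- stats::qnorm(p2)
  (bivariate_normal_cdf(t1, t2, rho) - p1 * p2) /
    sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Latent correlation achieving a target indicator correlation at given
# frequencies; capped at 0.9999 when the target is unreachable.
calibrate_latent_rho <- function(p1, p2, target) {
  if (target <= 1e-10) return(0)
  hi <- 0.9999
  f <- function(r) threshold_indicator_cor(p1, p2, r) - target
  if (f(hi) < 0) return(hi)
  stats::uniroot(f, c(0, hi), tol = 1e-8)$root
}

#' Simulate a block-LD genotype panel
#'
#' Draws per-haplotype alleles by thresholding a latent Gaussian AR(1)
#' process within each block at the target allele frequency, then sums two
#' independent haplotypes into dosages in `{0, 1, 2}`. The AR(1) correlation
#' of each adjacent pair is calibrated so the dosage correlation matches
#' `within_block_r`; blocks are mutually independent. Positions are laid out
#' on one chromosome with each block spanning under 300 kb and consecutive
#' blocks separated by more than 300 kb, so the default clumping window
#' never bridges blocks.
#'
#' @param config A [simulation_config()].
#' @param n Number of individuals (default: `n_cases + n_controls`).
#' @param seed Integer seed (default: taken from `config`).
#' @return A `genotype_panel`: list with `sample_ids`, `snp_meta`
#'   (data.frame: `id`, `chr`, `bp`, `a1`, `a2`, `freq`) and `dosages`
#'   (n × n_snps matrix of A1 counts).
#' @export
simulate_genotypes <- function(config, n = config$n_cases + config$n_controls,
                               seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"), n >= 1)
  set.seed(seed)
  m <- config$n_snps
  block_size <- ceiling(m / config$n_blocks)
  block_of <- rep(seq_len(config$n_blocks), each = block_size)[seq_len(m)]
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  # sort within block so adjacent SNPs have comparable frequencies
  for (b in unique(block_of)) {
    idx <- which(block_of == b)
    maf[idx] <- sort(maf[idx])
  }
  # latent AR(1) correlations for adjacent within-block pairs
  rho <- numeric(m)
  for (j in seq_len(m)[-1]) {
    if (block_of[j] == block_of[j - 1]) {
      rho[j] <- calibrate_latent_rho(maf[j - 1], maf[j], config$within_block_r)
    }
  }
  thr <- stats::qnorm(maf)
  dos <- matrix(0L, n, m)
  for (hap in 1:2) {
    z <- matrix(0, n, m)
    z[, 1] <- stats::rnorm(n)
    if (m > 1) {
      eps <- matrix(stats::rnorm(n * (m - 1)), n, m - 1)
      for (j in 2:m) {
        z[, j] <- if (rho[j] > 0) {
          rho[j] * z[, j - 1] + sqrt(1 - rho[j]^2) * eps[, j - 1]
        } else eps[, j - 1]
      }
    }
    dos <- dos + (z < matrix(thr, n, m, byrow = TRUE))
  }
  storage.mode(dos) <- "integer"
  # positions: blocks span < 300 kb, inter-block gaps > 300 kb
  bp <- integer(m)
  pos <- 1L
  for (j in seq_len(m)) {
    if (j > 1) {
      pos <- pos + if (block_of[j] == block_of[j - 1]) 5000L else 400000L
    }
    bp[j] <- pos
  }
  alleles <- sample_allele_pairs(m)
  meta <- data.frame(
    id = sprintf("rs%06d", seq_len(m)), chr = 1L, bp = bp,
    a1 = alleles$a1, a2 = alleles$a2, freq = maf,
    block = block_of, stringsAsFactors = FALSE
  )
  ids <- sprintf("S%05d", seq_len(n))
  rownames(dos) <- ids
  colnames(dos) <- meta$id
  structure(list(sample_ids = ids, snp_meta = meta, dosages = dos),
            class = "genotype_panel")
}

# Random allele pairs; includes strand-ambiguous (A/T, C/G) pairs at their
# natural rate so harmonization paths are exercised.
sample_allele_pairs <- function(m) {
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, m, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1))
  list(a1 = a1, a2 = unname(a2))
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$sample_ids), "samples x",
      nrow(x$snp_meta), "SNPs\n")
  invisible(x)
}

#' Draw true per-SNP effects for the synthetic cohort
#'
#' Selects `n_causal` SNPs and assigns standardized-genotype effect sizes
#' `N(0, h2_liability / n_causal)`; the per-allele true log odds ratio is the
#' standardized effect divided by the dosage SD implied by the allele
#' frequency.
#'
#' @param config A [simulation_config()].
#' @param snp_meta Panel SNP metadata (for allele frequencies).
#' @param seed Integer seed.
#' @return data.frame with `id`, `causal`, `beta_std`, `true_log_or`.
#' @export
simulate_true_effects <- function(config, snp_meta, seed = config$seed + 1L) {
  set.seed(seed)
  m <- nrow(snp_meta)
  causal <- sort(sample.int(m, config$n_causal))
  beta <- numeric(m)
  beta[causal] <- stats::rnorm(config$n_causal,
                               sd = sqrt(config$h2_liability / config$n_causal))
  sd_dos <- sqrt(2 * snp_meta$freq * (1 - snp_meta$freq))
  data.frame(id = snp_meta$id, causal = seq_len(m) %in% causal,
             beta_std = beta, true_log_or = beta / sd_dos,
             stringsAsFactors = FALSE)
}

#' Simulate discovery GWAS summary statistics
#'
#' Emulates a discovery meta-analysis: the estimated log odds ratio is the
#' true value plus Gaussian noise with variance
#' `1 / (2 * maf * (1 - maf) * n_eff)`, where
#' `n_eff = 4 / (1/n_cases + 1/n_controls)` is the effective sample size of
#' the discovery study; p-values are two-sided Wald.
#'
#' @param truth data.frame from [simulate_true_effects()] (needs `id`,
#'   `true_log_or`).
#' @param snp_meta Panel SNP metadata with `id`, `chr`, `bp`, `a1`, `a2`,
#'   `freq`.
#' @param config A [simulation_config()] supplying `n_discovery` and
#'   `discovery_case_frac`.
#' @param seed Integer seed.
#' @return `summary_stats` data.frame: `id`, `chr`, `bp`, `a1`, `a2`, `or`,
#'   `log_or`, `se`, `p`. SNPs with frequency 0 or 1 get `NA` estimates.
#' @export
simulate_discovery_sumstats <- function(truth, snp_meta, config,
                                        seed = config$seed + 2L) {
  stopifnot(all(snp_meta$id == truth$id))
  set.seed(seed)
  n_case <- config$n_discovery * config$discovery_case_frac
  n_ctrl <- config$n_discovery - n_case
  n_eff <- 4 / (1 / n_case + 1 / n_ctrl)
  maf <- snp_meta$freq
  se <- ifelse(maf > 0 & maf < 1,
               sqrt(1 / (2 * maf * (1 - maf) * n_eff)), NA_real_)
  est <- truth$true_log_or + stats::rnorm(nrow(snp_meta)) * se
  p <- 2 * stats::pnorm(-abs(est / se))
  out <- data.frame(
    id = snp_meta$id, chr = snp_meta$chr, bp = snp_meta$bp,
    a1 = snp_meta$a1, a2 = snp_meta$a2,
    or = exp(est), log_or = est, se = se, p = p,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Simulate environment measures (SLE items and CTQ items)
#'
#' Generates 12 binary stressful-life-event (SLE) indicators whose log odds
#' decrease with age and are higher in females, with a shared per-person
#' stress liability inducing item dependence, and 25 childhood-trauma
#' questionnaire (CTQ) items on a 1-5 Likert scale from a discretized latent
#' severity. Gene-environment correlation is injected by mixing a supplied
#' standardized genetic score into the latent liabilities
#' (`latent = rge * z_g + sqrt(1 - rge^2) * noise`).
#'
#' Items 1-7 are labelled behaviour-dependent and items 8-12 independent,
#' mirroring the 7 + 5 partition of the brief life-event questionnaire.
#'
#' @param config A [simulation_config()].
#' @param age,sex Per-sample covariates; `sex` coded 0 = male, 1 = female.
#' @param z_g Optional standardized genetic score for rGE injection
#'   (defaults to none).
#' @param seed Integer seed.
#' @return An `environment_profile`: list with `sle_items` (n × 12, 0/1),
#'   `ctq_items` (n × 25 in 1..5), `dependent_items` / `independent_items`
#'   column indices, plus convenience totals `sle_total`, `sle_dependent`,
#'   `sle_independent`, `ctq_total`.
#' @export
simulate_environment <- function(config, age, sex, z_g = NULL,
                                 seed = config$seed + 3L) {
  n <- length(age)
  stopifnot(length(sex) == n, is.null(z_g) || length(z_g) == n)
  set.seed(seed)
  rge <- config$rge
  mix <- function(u) if (is.null(z_g) || rge == 0) u else
    rge * z_g + sqrt(1 - rge^2) * u
  # SLE items: per-item intercepts spread so item prevalences differ
  intercepts <- seq(-2.6, -1.4, length.out = 12)
  u_sle <- mix(stats::rnorm(n))
  eta <- outer(rep(1, n), intercepts) +
    config$sle_age_slope * (age - 45) + config$sle_sex_effect * sex +
    config$sle_loading * u_sle
  sle <- matrix(stats::rbinom(n * 12L, 1L, stats::plogis(eta)), n, 12L)
  colnames(sle) <- c(paste0("dep", 1:7), paste0("indep", 1:5))
  # CTQ items: latent severity cut into ordinal categories (skewed low)
  u_ct <- mix(stats::rnorm(n))
  item_val <- 0.8 * u_ct + matrix(stats::rnorm(n * 25L, sd = 0.6), n, 25L)
  cuts <- stats::qnorm(cumsum(c(0.60, 0.20, 0.10, 0.06)), sd = 1)
  ctq <- matrix(1L, n, 25L)
  for (k in seq_along(cuts)) ctq <- ctq + (item_val > cuts[k])
  colnames(ctq) <- paste0("ctq", 1:25)
  structure(list(
    sle_items = sle, ctq_items = ctq,
    dependent_items = 1:7, independent_items = 8:12,
    sle_total = rowSums(sle),
    sle_dependent = rowSums(sle[, 1:7, drop = FALSE]),
    sle_independent = rowSums(sle[, 8:12, drop = FALSE]),
    ctq_total = rowSums(ctq)
  ), class = "environment_profile")
}

#' Simulate case-control status by retrospective sampling
#'
#' Case probability follows a logistic model in a standardized genetic score
#' and an environment variable,
#' `P(case) = plogis(b0 + log(or_g) z + log(or_e) e + log(or_gxe) z e)`;
#' exactly `n_cases` cases and `n_controls` controls are then sampled
#' without replacement from the source population.
#'
#' @param z_g Standardized genetic score (source population).
#' @param e Environment variable (source population), on the scale `or_e`
#'   refers to.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return list with `case` (0/1 for the sampled rows, cases first),
#'   `idx` (row indices into the source population) and the achieved counts.
#' @export
simulate_phenotype <- function(z_g, e, config, seed = config$seed + 4L) {
  n <- length(z_g)
  stopifnot(length(e) == n)
  set.seed(seed)
  eta <- config$baseline_logodds + log(config$or_g) * z_g +
    log(config$or_e) * e + log(config$or_gxe) * z_g * e
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  cases <- which(y == 1L); ctrls <- which(y == 0L)
  if (length(cases) < config$n_cases || length(ctrls) < config$n_controls) {
    stop(sprintf(
      "case/control quota unreachable: drew %d cases and %d controls, need %d/%d",
      length(cases), length(ctrls), config$n_cases, config$n_controls))
  }
  idx <- c(sample(cases, config$n_cases), sample(ctrls, config$n_controls))
  list(case = rep(c(1L, 0L), c(config$n_cases, config$n_controls)),
       idx = idx, n_cases = config$n_cases, n_controls = config$n_controls)
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generative model: source population covariates, block-LD
#' genotypes, true SNP effects, noisy discovery summary statistics,
#' environment measures (with optional gene-environment correlation),
#' logistic case-control sampling, interview mood scores, and optional
#' recall-bias inflation of reported life events in severely depressed cases.
#'
#' @param config A [simulation_config()].
#' @return list with elements `panel` (sampled `genotype_panel`), `sumstats`,
#'   `truth`, `phenotype` (data.frame: `sample_id`, `case`, `age`, `sex`,
#'   `bdi`), `env` (`environment_profile` for the sampled rows), and
#'   `z_true` (standardized true score of sampled rows).
#' @export
simulate_cohort <- function(config) {
  n_target <- config$n_cases + config$n_controls
  n_pop <- ceiling(config$pop_multiplier * n_target)
  set.seed(config$seed)
  age <- pmin(pmax(round(stats::rnorm(n_pop, 45, 13)), 18), 85)
  sex <- stats::rbinom(n_pop, 1L, 0.55)

  panel <- simulate_genotypes(config, n = n_pop, seed = config$seed + 10L)
  truth <- simulate_true_effects(config, panel$snp_meta)
  sumstats <- simulate_discovery_sumstats(truth, panel$snp_meta, config)

  # standardized true score from causal SNPs on the standardized-dosage scale
  causal <- which(truth$causal)
  g <- panel$dosages[, causal, drop = FALSE]
  g_std <- scale(g)
  g_std[, attr(g_std, "scaled:scale") == 0] <- 0
  raw <- as.vector(g_std %*% truth$beta_std[causal])
  z_g <- if (stats::sd(raw) > 0) as.vector(scale(raw)) else raw

  env <- simulate_environment(config, age, sex, z_g = z_g)
  e <- switch(config$env_kind,
    sle2plus  = as.numeric(env$sle_total >= 2),
    sle_count = env$sle_total,
    ctq_total = as.vector(scale(env$ctq_total))
  )
  ph <- simulate_phenotype(z_g, e, config)
  idx <- ph$idx

  set.seed(config$seed + 5L)
  # interview mood: controls screened to BDI < 10; case severity tracks
  # polygenic liability so mood-at-interview sensitivity scenarios are
  # coherent
  bdi <- integer(length(idx))
  bdi[ph$case == 0L] <- sample(0:9, sum(ph$case == 0L), replace = TRUE)
  is_case <- ph$case == 1L
  bdi[is_case] <- pmin(pmax(round(stats::rnorm(
    sum(is_case), 22 + 3 * z_g[idx[is_case]], 9)), 0), 63)

  env_s <- subset_environment(env, idx)
  if (config$recall_bias > 0) {
    env_s <- apply_recall_bias(env_s, case = ph$case, bdi = bdi,
                               strength = config$recall_bias)
  }
  panel_s <- structure(list(
    sample_ids = panel$sample_ids[idx],
    snp_meta = panel$snp_meta,
    dosages = panel$dosages[idx, , drop = FALSE]
  ), class = "genotype_panel")

  phenotype <- data.frame(
    sample_id = panel$sample_ids[idx], case = ph$case,
    age = age[idx], sex = sex[idx], bdi = bdi,
    stringsAsFactors = FALSE
  )
  list(panel = panel_s, sumstats = sumstats, truth = truth,
       phenotype = phenotype, env = env_s, z_true = z_g[idx],
       config = config)
}

# Row-subset an environment_profile.
subset_environment <- function(env, idx) {
  sle <- env$sle_items[idx, , drop = FALSE]
  ctq <- env$ctq_items[idx, , drop = FALSE]
  structure(list(
    sle_items = sle, ctq_items = ctq,
    dependent_items = env$dependent_items,
    independent_items = env$independent_items,
    sle_total = rowSums(sle),
    sle_dependent = rowSums(sle[, env$dependent_items, drop = FALSE]),
    sle_independent = rowSums(sle[, env$independent_items, drop = FALSE]),
    ctq_total = rowSums(ctq)
  ), class = "environment_profile")
}

#' Inflate reported life events in severely depressed cases
#'
#' Models recall bias at interview: for cases, each unreported SLE item is
#' flipped to reported with probability `strength * pmax(bdi - 10, 0) / 53`,
#' so only low-mood cases over-report. Used to build sensitivity-analysis
#' scenarios.
#'
#' @param env An `environment_profile`.
#' @param case 0/1 case status.
#' @param bdi Interview mood score (0-63).
#' @param strength Flip-probability scale in `[0, 1]`.
#' @return The modified `environment_profile`.
#' @export
apply_recall_bias <- function(env, case, bdi, strength) {
  stopifnot(strength >= 0, strength <= 1)
  sle <- env$sle_items
  n <- nrow(sle)
  p_flip <- strength * pmax(bdi - 10, 0) / 53 * (case == 1L)
  flips <- matrix(stats::rbinom(n * ncol(sle), 1L, rep(p_flip, ncol(sle))),
                  n, ncol(sle))
  sle <- pmax(sle, flips)
  env$sle_items <- sle
  env$sle_total <- rowSums(sle)
  env$sle_dependent <- rowSums(sle[, env$dependent_items, drop = FALSE])
  env$sle_independent <- rowSums(sle[, env$independent_items, drop = FALSE])
  env
}
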