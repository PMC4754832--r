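#' Load and validate a pipeline run configuration
#'
#' The configuration is a named list (or a YAML file holding one) with
#' blocks per stage. Unknown keys, at the top level or inside a block, are
#' errors so parameter-name typos cannot silently fall back to defaults.
#'
#' Recognized top-level keys: `seed`, `stages`, `simulation`, `clump`,
#' `grid`, `plan`, `pcs_k`, `ctq_cutpoints`, `bdi_threshold`, `power`
#' (a list of scenario blocks).
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config list with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("seed", "stages", "simulation", "clump", "grid", "plan",
             "pcs_k", "ctq_cutpoints", "bdi_threshold", "power")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  }
  check_block <- function(block, fun, name) {
    if (is.null(block)) return(list())
    bad <- setdiff(names(block), names(formals(fun)))
    if (length(bad) > 0) {
      stop("unknown key(s) in '", name, "': ", paste(bad, collapse = ", "))
    }
    block
  }
  config$simulation <- check_block(config$simulation, simulation_config,
                                   "simulation")
  config$clump <- check_block(config$clump, clump_params, "clump")
  config$plan <- check_block(config$plan, analysis_plan, "plan")
  if (!is.null(config$power)) {
    config$power <- lapply(config$power, check_block, fun = power_scenario,
                           name = "power")
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$stages)) {
    config$stages <- c("simulate", "clump", "score", "prepare", "gxe",
                       "power")
  }
  stopifnot(all(config$stages %in%
                  c("simulate", "clump", "score", "prepare", "gxe", "power")))
  if (is.null(config$pcs_k)) config$pcs_k <- 2L
  if (is.null(config$bdi_threshold)) config$bdi_threshold <- 29
  if (is.null(config$ctq_cutpoints)) config$ctq_cutpoints <- c(31, 51)
  config
}

# Derive a deterministic per-stage seed from the global one.
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, clump = 0L, score = 0L, prepare = 211L,
            gxe = 307L, power = 401L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order: `simulate` (synthetic
#' cohort), `clump` (LD clumping of discovery summary statistics against the
#' cohort panel), `score` (allele harmonization and polygenic scoring over
#' the threshold grid), `prepare` (PCs, genomic control, age imputation, SLE
#' adjustment, CTQ scoring), `gxe` (all interaction and correlation models),
#' and `power` (scenario power estimates). Every output table carries a
#' `#`-prefixed header with the config hash and seed; a run report lists
#' per-stage record counts and warnings.
#'
#' @param config Named list or YAML path; see [load_run_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisible list: the run report plus the in-memory stage outputs.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  meta <- c(config_hash = cfg_hash, seed = cfg$seed)
  report <- list()
  state <- list()
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  if ("simulate" %in% cfg$stages) {
    tryCatch({
      sim_cfg <- do.call(simulation_config,
                         c(cfg$simulation,
                           list(seed = stage_seed(cfg$seed, "simulate"))))
      state$cohort <- simulate_cohort(sim_cfg)
      write_daner(state$cohort$sumstats, file.path(out_dir, "sumstats.daner"))
      write_dosage_raw(state$cohort$panel, file.path(out_dir, "genotypes.raw"))
      write_bim(state$cohort$panel, file.path(out_dir, "genotypes.bim"))
      write_tsv_meta(state$cohort$phenotype,
                     file.path(out_dir, "phenotype.tsv"), meta)
      env <- state$cohort$env
      env_tab <- data.frame(sample_id = state$cohort$phenotype$sample_id,
                            env$sle_items, env$ctq_items,
                            check.names = FALSE)
      write_tsv_meta(env_tab, file.path(out_dir, "environment.tsv"), meta)
      report$simulate <- list(n_samples = nrow(state$cohort$phenotype),
                              n_snps = nrow(state$cohort$panel$snp_meta))
    }, error = function(e) fail("simulate", e))
  }

  if ("clump" %in% cfg$stages) {
    tryCatch({
      if (is.null(state$cohort)) state$cohort <- read_cohort_dir(out_dir)
      params <- do.call(clump_params, cfg$clump)
      state$clumped <- clump(state$cohort$sumstats, state$cohort$panel,
                             params)
      clump_tab <- data.frame(
        index_snp = state$clumped$index_snps,
        n_members = vapply(state$clumped$index_snps, function(i) {
          length(state$clumped$members[[i]])
        }, integer(1)),
        members = vapply(state$clumped$index_snps, function(i) {
          paste(state$clumped$members[[i]], collapse = ",")
        }, character(1))
      )
      write_tsv_meta(clump_tab, file.path(out_dir, "clumps.tsv"), meta)
      report$clump <- list(n_index = length(state$clumped$index_snps),
                           n_retained = length(state$clumped$retained))
    }, error = function(e) fail("clump", e))
  }

  if ("score" %in% cfg$stages) {
    tryCatch({
      grid <- if (is.null(cfg$grid)) threshold_grid() else
        threshold_grid(as.numeric(cfg$grid))
      state$weights <- align_alleles(state$cohort$sumstats,
                                     state$cohort$panel)
      state$scores <- score_grid(state$cohort$panel, state$weights,
                                 state$cohort$sumstats, grid,
                                 retained = state$clumped$retained)
      tab <- data.frame(sample_id = rownames(state$scores$raw),
                        state$scores$raw, state$scores$std,
                        check.names = FALSE)
      names(tab) <- c("sample_id", paste0("raw_", colnames(state$scores$raw)),
                      paste0("std_", colnames(state$scores$std)))
      write_tsv_meta(tab, file.path(out_dir, "scores.tsv"), meta)
      report$score <- list(n_snps_per_threshold = state$scores$n_snps)
    }, error = function(e) fail("score", e))
  }

  if ("prepare" %in% cfg$stages) {
    tryCatch({
      ph <- state$cohort$phenotype
      env <- state$cohort$env
      pcs <- compute_pcs(state$cohort$panel, k = cfg$pcs_k)
      age <- impute_missing_age(ph$age, ph$sex, ph$case)
      adj <- adjust_sle_counts(
        cbind(total = env$sle_total, dependent = env$sle_dependent,
              independent = env$sle_independent),
        age$age, ph$sex, ph$case)
      ctq <- ctq_score(env$ctq_items, cutpoints = cfg$ctq_cutpoints)
      state$prepared <- list(
        pcs = pcs, age = age$age,
        sle_total_adj = adj[, "total"], sle_dep_adj = adj[, "dependent"],
        sle_indep_adj = adj[, "independent"],
        ctq_total = ctq$ctq_total, ct_category = ctq$ct_category)
      cov_tab <- data.frame(sample_id = ph$sample_id, pcs, age = age$age,
                            age_imputed = age$age_imputed, sex = ph$sex,
                            bdi = ph$bdi)
      write_tsv_meta(cov_tab, file.path(out_dir, "covariates.tsv"), meta)
      env_tab <- data.frame(
        sample_id = ph$sample_id,
        sle_total = env$sle_total, sle_dependent = env$sle_dependent,
        sle_independent = env$sle_independent,
        sle_total_adj = adj[, "total"], sle_dep_adj = adj[, "dependent"],
        sle_indep_adj = adj[, "independent"],
        ctq_total = ctq$ctq_total, ct_category = as.character(ctq$ct_category))
      write_tsv_meta(env_tab, file.path(out_dir, "environment_prepared.tsv"),
                     meta)
      report$prepare <- list(n_pcs = ncol(pcs),
                             n_age_imputed = sum(age$age_imputed))
    }, error = function(e) fail("prepare", e))
  }

  if ("gxe" %in% cfg$stages) {
    tryCatch({
      plan <- do.call(analysis_plan,
                      c(cfg$plan,
                        list(grid = state$scores$grid,
                             seed = stage_seed(cfg$seed, "gxe"))))
      pr <- state$prepared
      envs <- list(sle_total_adj = pr$sle_total_adj,
                   sle_dep_adj = pr$sle_dep_adj,
                   sle_indep_adj = pr$sle_indep_adj,
                   ctq_total = pr$ctq_total)
      y <- state$cohort$phenotype$case
      state$gxe <- run_threshold_grid(plan, state$scores, envs, pr$pcs, y,
                                      ct_category = pr$ct_category)
      write_tsv_meta(state$gxe$results, file.path(out_dir, "gxe_results.tsv"),
                     meta)
      write_tsv_meta(state$gxe$bar_data,
                     file.path(out_dir, "fig_variance_by_threshold.tsv"),
                     meta)
      if (!is.null(state$gxe$curve_data)) {
        write_tsv_meta(state$gxe$curve_data,
                       file.path(out_dir, "fig_logodds_by_category.tsv"),
                       meta)
      }
      report$gxe <- list(n_results = nrow(state$gxe$results),
                         bonferroni = state$gxe$bonferroni)
    }, error = function(e) fail("gxe", e))
  }

  if ("power" %in% cfg$stages && !is.null(cfg$power)) {
    tryCatch({
      rows <- lapply(seq_along(cfg$power), function(i) {
        sc <- do.call(power_scenario,
                      c(cfg$power[[i]],
                        list(seed = stage_seed(cfg$seed, "power") + i)))
        est <- estimate_power(sc)
        data.frame(n_cases = sc$n_cases, n_controls = sc$n_controls,
                   or_g = sc$or_g, or_e = sc$or_e, or_gxe = sc$or_gxe,
                   env_kind = sc$env_kind, alpha = sc$alpha,
                   n_reps = est$n_reps_used, power = est$power,
                   mc_se = est$mc_se)
      })
      state$power <- do.call(rbind, rows)
      write_tsv_meta(state$power, file.path(out_dir, "power.tsv"), meta)
      report$power <- list(n_scenarios = nrow(state$power))
    }, error = function(e) fail("power", e))
  }

  out <- list(report = report, state = state, config = cfg,
              config_hash = cfg_hash)
  invisible(out)
}

# Reload persisted simulation outputs so later stages can resume from disk.
read_cohort_dir <- function(out_dir) {
  daner <- file.path(out_dir, "sumstats.daner")
  raw <- file.path(out_dir, "genotypes.raw")
  bim <- file.path(out_dir, "genotypes.bim")
  ph <- file.path(out_dir, "phenotype.tsv")
  ev <- file.path(out_dir, "environment.tsv")
  if (!all(file.exists(daner, raw, bim, ph, ev))) {
    stop("no cohort in memory and no persisted simulation outputs in ",
         out_dir)
  }
  env_tab <- read_tsv_meta(ev)
  sle <- as.matrix(env_tab[, grep("^(dep|indep)", names(env_tab))])
  ctq <- as.matrix(env_tab[, grep("^ctq", names(env_tab))])
  env <- structure(list(
    sle_items = sle, ctq_items = ctq,
    dependent_items = 1:7, independent_items = 8:12,
    sle_total = rowSums(sle),
    sle_dependent = rowSums(sle[, 1:7, drop = FALSE]),
    sle_independent = rowSums(sle[, 8:12, drop = FALSE]),
    ctq_total = rowSums(ctq)), class = "environment_profile")
  list(sumstats = read_daner(daner),
       panel = read_dosage_raw(raw, bim),
       phenotype = read_tsv_meta(ph),
       env = env)
}
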