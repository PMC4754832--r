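#!/usr/bin/env Rscript
# Stage 3: prepare covariates and environments — ancestry principal
# components, genomic-control check, sex-stratified age imputation,
# control-coefficient adjustment of stressful-life-event counts in cases,
# and childhood-trauma questionnaire scoring. Writes
# results/run/covariates.tsv and results/run/environment_prepared.tsv.

library(prsgxe)

out_dir <- "results/run"
cohort <- prsgxe:::read_cohort_dir(out_dir)
ph <- cohort$phenotype
env <- cohort$env

pcs <- compute_pcs(cohort$panel, k = 2)
# genomic control on per-SNP trend statistics: a quarter of the panel is
# truly causal here, so lambda far above 1 reflects genuine polygenic
# signal, not stratification (the panel has a single ancestry)
keep <- apply(cohort$panel$dosages, 2, sd) > 0
chi <- (nrow(pcs) - 1) *
  as.vector(cor(cohort$panel$dosages[, keep], ph$case))^2
cat("genomic-control lambda (true polygenic signal, one ancestry):",
    round(genomic_control_lambda(chi), 3), "\n")

age <- impute_missing_age(ph$age, ph$sex, ph$case)
adj <- adjust_sle_counts(
  cbind(total = env$sle_total, dependent = env$sle_dependent,
        independent = env$sle_independent),
  age$age, ph$sex, ph$case)
fits <- attr(adj, "fits")
cat("control regression of SLE total on age, sex:",
    sprintf("b_age = %.4f, b_sex = %.3f\n", fits[[1]][2], fits[[1]][3]))
ctq <- ctq_score(env$ctq_items)
cat("CT categories:", paste(names(table(ctq$ct_category)),
                            table(ctq$ct_category), collapse = ", "), "\n")

write_tsv_meta(data.frame(sample_id = ph$sample_id, pcs, age = age$age,
                          age_imputed = age$age_imputed, sex = ph$sex,
                          bdi = ph$bdi),
               file.path(out_dir, "covariates.tsv"), c(seed = 1))
write_tsv_meta(data.frame(
  sample_id = ph$sample_id,
  sle_total = env$sle_total, sle_dependent = env$sle_dependent,
  sle_independent = env$sle_independent,
  sle_total_adj = adj[, "total"], sle_dep_adj = adj[, "dependent"],
  sle_indep_adj = adj[, "independent"],
  ctq_total = ctq$ctq_total, ct_category = as.character(ctq$ct_category)),
  file.path(out_dir, "environment_prepared.tsv"), c(seed = 1))
cat("written: covariates.tsv, environment_prepared.tsv\n")
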