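#!/usr/bin/env Rscript
# Stage 2: LD-clump the discovery summary statistics against the cohort's
# own genotypes (p1 0.5, p2 0.1, r2 0.25, 300 kb window), harmonize effect
# alleles, and build log-OR-weighted polygenic scores at the nine p-value
# thresholds. Writes results/run/clumps.tsv and results/run/scores.tsv.

library(prsgxe)

out_dir <- "results/run"
cohort <- prsgxe:::read_cohort_dir(out_dir)

ci <- clump(cohort$sumstats, cohort$panel, clump_params())
cat("clumping:", length(ci$index_snps), "index SNPs,",
    sum(lengths(ci$members)), "SNPs removed as members,",
    length(ci$retained), "retained\n")

weights <- align_alleles(cohort$sumstats, cohort$panel)
scores <- score_grid(cohort$panel, weights, cohort$sumstats,
                     retained = ci$retained)
cat("SNPs per threshold:", paste(scores$n_snps, collapse = ", "), "\n")

clump_tab <- data.frame(
  index_snp = ci$index_snps,
  n_members = vapply(ci$index_snps,
                     function(i) length(ci$members[[i]]), integer(1)),
  members = vapply(ci$index_snps,
                   function(i) paste(ci$members[[i]], collapse = ","),
                   character(1)))
write_tsv_meta(clump_tab, file.path(out_dir, "clumps.tsv"), c(seed = 1))
tab <- data.frame(sample_id = rownames(scores$raw), scores$raw, scores$std,
                  check.names = FALSE)
names(tab) <- c("sample_id", paste0("raw_", colnames(scores$raw)),
                paste0("std_", colnames(scores$std)))
write_tsv_meta(tab, file.path(out_dir, "scores.tsv"), c(seed = 1))
cat("written: clumps.tsv, scores.tsv\n")
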