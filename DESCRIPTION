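Package: prsgxe
Title: Polygenic Score by Environment Interaction Analysis for Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing interactions between polygenic risk scores and
    environmental adversity in case-control designs. Implements p-value-informed
    LD clumping of discovery GWAS summary statistics against a validation
    genotype panel, log odds-ratio weighted polygenic scoring over a grid of
    p-value thresholds, ancestry principal components and genomic-control
    inflation, age and sex adjustment of stressful life event counts using
    control-estimated coefficients, childhood trauma questionnaire scoring,
    multiplicative and additive gene-environment interaction models with
    Nagelkerke pseudo-R-squared attribution and permutation empirical p-values,
    gene-environment correlation tests, simulation-based power analysis, and a
    synthetic cohort generator with block-LD genotypes, noisy discovery effect
    estimates and configurable interaction effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
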