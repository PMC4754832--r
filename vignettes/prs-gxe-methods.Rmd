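---
title: "Methods: polygenic score by environment interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic score by environment interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`prsgxe` implements a complete case-control pipeline for testing whether
polygenic liability to major depressive disorder (MDD) interacts with
environmental adversity — adult stressful life events (SLEs) and childhood
trauma (CT) — from discovery GWAS summary statistics through LD clumping,
thresholded polygenic scoring, covariate preparation, multiplicative and
additive interaction models with permutation inference, to simulation-based
power analysis. Because individual-level clinical and genotype data of this
kind cannot be redistributed, the package ships a synthetic-cohort generator
that reproduces the statistical structure the analysis assumes; every stage
is developed and tested against it.

# The models

## Polygenic scores

A polygenic risk score (PRS) for person $i$ is the weighted allele count

$$\mathrm{PRS}_i = \sum_{j \in S(p_T)} \hat\beta_j \, g_{ij},$$

where $g_{ij} \in [0,2]$ is the dosage of the discovery study's effect
allele, $\hat\beta_j$ its discovery log odds ratio, and $S(p_T)$ the set of
clumped SNPs with discovery $p < p_T$. Nine thresholds are used
(0.0001–0.5). Clumping follows the PLINK greedy convention with defaults
`p1 = 0.5`, `p2 = 0.1`, `r2 = 0.25`, `kb = 300`: SNPs with $p < p_1$ are
visited in order of significance; each unassigned visit becomes a clump
index and removes every unassigned SNP with $p < p_2$ within the window
whose squared dosage correlation with it exceeds `r2`. SNPs with
$p_2 \le p < p_1$ can index a clump but are never removed by a stronger
index; whether scoring should use index SNPs only is genuinely ambiguous in
PRS practice, so `clump(index_only = TRUE)` exposes the alternative while
the default keeps every SNP not removed as a member. Ties on $p$ break by
(chromosome, position, id) so the result is order-invariant. Effect alleles
are harmonized before scoring (`matched`, `flipped`, `strand_flipped`,
with A/T and C/G SNPs dropped as strand-ambiguous); missing dosages are
mean-imputed as twice the panel allele frequency, and scores are
standardized to mean 0, SD 1 over the full analysis sample. Standardized
scores are used throughout the models, not only for plotting; `score_grid`
returns both scales for anyone wanting the alternative.

## Interaction and correlation models

With $y$ the 0/1 case status, $Z$ the standardized PRS and $E$ the
environment measure, the multiplicative model is the logistic regression

$$\mathrm{logit}\,P(y=1) = \beta_0 + \beta_Z Z + \beta_E E +
  \sum_k \gamma_k \mathrm{PC}_k + \sum_k \delta_k (\mathrm{PC}_k E) +
  \sum_k \eta_k (\mathrm{PC}_k Z) + \beta_{ZE}\, ZE,$$

whose product term carries the interaction; the PC × covariate products
guard against stratification-driven artifacts. Variance explained by any
term is the Nagelkerke pseudo-$R^2$ difference between the model with and
without that term, both computed against the intercept-only null — with PCs
as the only other covariates this is "variance explained excluding the
PCs". The additive model fits the identical design by least squares on the
0/1 outcome (a linear probability model) and reports the product term's
coefficient and multiple-$R^2$ increment. Gene-environment correlation (rGE)
regresses $E$ on $Z$ and the PCs within a subset (cases by default, since
selection into adversity is the hypothesis of interest). Empirical p-values
for every model come from permuting the outcome vector while keeping the
$(Z, E, \mathrm{PC})$ rows intact, which preserves the gene-environment
joint distribution while breaking both main and interaction associations;
$p = (1 + \#\{|t^{(b)}| \ge |t|\})/(B+1)$. Term-specific residual
permutation is a defensible alternative; outcome permutation was chosen
because it is exact under the strong null and applies uniformly to every
model in the plan. Ten planned tests give the shipped Bonferroni threshold
$0.05/10 = 0.005$; the divisor follows the analysis plan when that differs.

The PRS main effect uses the same machinery without the product terms; the
environment main effect likewise. A sensitivity wrapper re-runs any analysis
with severely depressed cases removed (interview mood score at or above a
configurable threshold, default 29, the conventional severe band of the
instrument).

## Covariates and environments

Principal components are the top left singular vectors of the per-SNP
centred, variance-standardized dosage matrix (mean-imputed, monomorphic
SNPs dropped), unit norm, sign fixed so each component's largest-magnitude
coordinate is positive — components are sign-ambiguous and the models are
sign-invariant, but a convention makes runs reproducible. The
genomic-control factor is $\lambda = \mathrm{median}(\chi^2)/0.4549$.
Missing ages are replaced by the sex-specific mean within case/control
group. SLE counts in cases are adjusted with control-estimated
coefficients: a least-squares fit of count on age and sex (male = 0,
female = 1) in controls, then
$\mathrm{adj} = \mathrm{obs} - \hat b_{\mathrm{age}}(\mathrm{age} -
\bar{\mathrm{age}}_{\mathrm{ctrl}}) - \hat b_{\mathrm{sex}}(\mathrm{sex} -
\bar{\mathrm{sex}}_{\mathrm{ctrl}})$ for cases only, each of total,
dependent (7 items) and independent (5 items) counts with its own fit.
Centring at the control means is a deliberate convention: it makes a case
at the control mean age and sex keep its observed count. CT totals sum 25
Likert items (1–5, range 25–125); up to 10% missing items are prorated by
the person's item mean (common questionnaire practice); the
none/mild/moderate-severe categories use configurable total-score
cut-points (defaults 31 and 51) because category definitions vary across
cohorts and instruments — all interaction models use the quantitative
total, so the cut-points only affect the descriptive figure.

# The synthetic cohort

The generator's defaults are the design points the package is validated
against: 1605 cases and 1064
controls (240/272 in CT analyses), a discovery meta-analysis of 7615 cases
and 7931 controls, PRS odds ratio 1.22 per SD, environment odds ratios 1.82
(two or more SLEs) and 2.27 (moderate/severe CT), and candidate interaction
odds ratios 1.28 and 1.76.

* **Genotypes.** 400 SNPs in 40 blocks; within a block, per-haplotype
  alleles come from thresholding a latent Gaussian AR(1) process at the
  target allele frequency (drawn uniformly on 0.05–0.5 and sorted within
  block so adjacent SNPs have comparable frequencies, as LD partners do).
  The latent correlation of each adjacent pair is calibrated numerically so
  the *dosage* correlation matches the configured 0.8 — naive thresholding
  attenuates it. Blocks span under 300 kb and sit more than 300 kb apart,
  so the default clumping window never bridges blocks.
* **Discovery statistics.** Estimated log odds ratios are true values plus
  Gaussian noise with $\mathrm{se}^2 = 1/(2\,\mathrm{maf}(1-\mathrm{maf})
  n_\mathrm{eff})$, $n_\mathrm{eff} = 4/(1/n_\mathrm{cases} +
  1/n_\mathrm{controls})$ — the standard GWAS approximation, adequate for
  emulating noisy weights. 100 of 400 SNPs are causal with standardized
  effects of variance $h^2/n_\mathrm{causal}$ ($h^2 = 0.3$, within the
  heritability range reported for MDD).
* **Environments.** Twelve Bernoulli SLE items whose log odds fall with age
  (−0.02/year) and rise for females (+0.25), matching the reported
  demographic structure of event counts; a shared per-person stress
  liability (loading 0.8) makes items positively dependent, as real
  questionnaires are. Twenty-five CT items discretize a latent severity
  into a right-skewed 1–5 distribution. Gene-environment correlation is
  injected actively: the environment latents are mixed with the true
  standardized genetic score, $u = r_{GE} Z + \sqrt{1-r_{GE}^2}\,
  \varepsilon$, matching the interpretation that liability drives selection
  into adversity.
* **Disease and sampling.** $P(\mathrm{case}) = \mathrm{logit}^{-1}(\beta_0
  + \log\mathrm{OR}_G Z + \log\mathrm{OR}_E E + \log\mathrm{OR}_{GE} ZE)$
  in a source population 20× the target size, then exact case/control
  quotas are drawn without replacement. $\beta_0 = \mathrm{logit}(0.10)$ is
  the risk at mean PRS and no exposure; with the default exposure
  prevalences this implies a marginal prevalence near 13–14%, the standard
  lifetime figure for MDD. The intercept is exposed as a free parameter
  because assumed population risk is the least standardized quantity in
  published power calculations of this kind. Interview mood scores are generated so that case severity tracks
  polygenic liability, and an optional recall-bias mechanism inflates
  reported events in low-mood cases, which is what the mood-at-interview
  sensitivity analysis is designed to catch.

What the generator does **not** emulate: realistic human LD maps and allele
frequency spectra, imputation uncertainty, X-chromosome inheritance,
relatedness, genotyping batch effects, multi-ancestry structure (a
stratified panel is built ad hoc in the tests where needed), and item-level
psychometrics of the questionnaires beyond marginal skew and dependence.
Passing tests therefore demonstrate that the statistical machinery is
correct under the stated generative model, not that the scientific findings
of any particular cohort would replicate.

# Power analysis

Power is estimated by direct simulation rather than analytic approximation:
per replicate, draw a standardized score and a binary exposure, assign case
status from the logistic model, sample to the case/control quotas, fit the
multiplicative model without PCs (the power design has no stratification)
and record Wald rejection of the product term at $\alpha$. Exposure
prevalences default to 0.45 (two or more SLEs) and 0.30 (moderate/severe
CT), consistent with sample-characteristic marginals. At 1000 replicates
the full-cohort scenario (OR 1.28) gives power around 0.84. The CT-subset
scenario (OR 1.76 at 240/272) sits on the 80% boundary: across disease
prevalences 5–20% and exposure prevalences 0.2–0.6 the estimate stays
within roughly 0.78–0.82, so whether it clears a nominal 80% target
depends on parameterization details (assumed population risk, exposure
prevalence, test statistic) that analytic power programs fix differently.
The estimate is reported as measured rather than adjusted toward a target.

# Numerical choices and problem sizes

Logistic models are fitted by iteratively reweighted least squares
(convergence tolerance 1e-10, up to 200 iterations), with standard errors
from the observed information. Rank-deficient designs are an error naming
the redundant column. Separation is flagged when any per-SD effect exceeds
15 on the log-odds scale — raw coefficients are deliberately not used,
because unit-norm PC columns legitimately carry large raw coefficients.
Permutation refits that fail are discarded; more than 5% failures is an
error. Standardized score columns with zero variance are left at zero and
flagged. Monomorphic SNPs have LD $r^2$ defined as 0 (they cannot evidence
LD) and never join clumps.

Test-suite problem sizes are chosen to keep the full suite around two
minutes while leaving Monte-Carlo error well inside every asserted band:
calibration and uniformity checks use 1000 replicates at a few hundred
samples; recovery checks use 200 replicates at the study sizes;
the clumping oracle covers 100 random instances of up to 20 SNPs; the
end-to-end pipeline check runs the shipped configuration at the full
2669-sample design with 29 permutations per model.
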