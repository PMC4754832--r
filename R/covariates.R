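#' Ancestry principal components from a dosage matrix
#'
#' Mean-imputes missing dosages per SNP, drops monomorphic SNPs, centres and
#' variance-standardizes each SNP column, and returns the top-k left singular
#' directions (unit norm per component). The sign of each component is fixed
#' so that its largest-magnitude coordinate is positive.
#'
#' @param panel A `genotype_panel` or a numeric sample × SNP matrix.
#' @param k Number of components (default 2).
#' @return n × k matrix with columns `PC1..PCk`; singular values of the
#'   standardized matrix as attribute `d`.
#' @export
compute_pcs <- function(panel, k = 2) {
  m <- if (inherits(panel, "genotype_panel")) panel$dosages else panel
  m <- as.matrix(m)
  stopifnot(nrow(m) >= k + 1)
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    for (j in which(colSums(is.na(m)) > 0)) m[is.na(m[, j]), j] <- mu[j]
  }
  sds <- apply(m, 2, stats::sd)
  m <- m[, sds > 0, drop = FALSE]
  x <- scale(m)
  sv <- svd(x, nu = k, nv = 0)
  if (k > sum(sv$d > 1e-8)) stop("k exceeds the rank of the dosage matrix")
  u <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (u[which.max(abs(u[, j])), j] < 0) u[, j] <- -u[, j]
  }
  colnames(u) <- paste0("PC", seq_len(k))
  rownames(u) <- rownames(m)
  attr(u, "d") <- sv$d[seq_len(k)]
  u
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi2) / 0.4549364`, the null median of a 1-df chi-square.
#' P-values are converted through the inverse upper-tail chi-square.
#'
#' @param chisq Per-SNP 1-df association chi-square statistics.
#' @param p Alternatively, per-SNP p-values.
#' @return The inflation factor (values near 1 indicate no stratification).
#' @export
genomic_control_lambda <- function(chisq = NULL, p = NULL) {
  if (is.null(chisq)) {
    stopifnot(!is.null(p), all(p > 0 & p <= 1, na.rm = TRUE))
    chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  chisq <- chisq[!is.na(chisq)]
  stopifnot(length(chisq) >= 1)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Impute missing ages by sex within case/control group
#'
#' Missing ages are replaced by the mean age of the same sex within the same
#' group (cases use age at worst episode, controls age at interview; the
#' caller supplies whichever is recorded).
#'
#' @param age Numeric vector with possible `NA`.
#' @param sex 0 = male, 1 = female.
#' @param case 0/1 group indicator.
#' @return data.frame with `age` (imputed) and logical `age_imputed`.
#' @export
impute_missing_age <- function(age, sex, case) {
  n <- length(age)
  stopifnot(length(sex) == n, length(case) == n)
  imputed <- is.na(age)
  for (g in unique(case)) {
    for (s in unique(sex)) {
      sel <- case == g & sex == s
      if (!any(sel)) next
      if (all(is.na(age[sel]))) {
        stop("no observed ages for sex ", s, " in group ", g)
      }
      age[sel & imputed] <- mean(age[sel], na.rm = TRUE)
    }
  }
  data.frame(age = age, age_imputed = imputed)
}

#' Adjust case SLE counts for age and sex using control coefficients
#'
#' Fits, in controls only, a least-squares regression of the event count on
#' age and sex (male = 0, female = 1), then removes the fitted age/sex
#' contribution from case counts, centring at the control means:
#' `adjusted = observed - b_age * (age - mean_age_ctrl)
#'  - b_sex * (sex - mean_sex_ctrl)`. Controls keep their observed counts.
#' Each count column (e.g. total, dependent, independent) gets its own fit.
#'
#' @param counts Numeric vector or matrix/data.frame of event counts.
#' @param age,sex,case Per-sample covariates and 0/1 status.
#' @return Matrix (or vector, matching input) of adjusted counts; the
#'   control fits are attached as attribute `fits`.
#' @export
adjust_sle_counts <- function(counts, age, sex, case) {
  vec_in <- is.null(dim(counts))
  m <- as.matrix(counts)
  n <- nrow(m)
  stopifnot(length(age) == n, length(sex) == n, length(case) == n,
            any(case == 0))
  ctrl <- case == 0
  if (stats::var(age[ctrl]) == 0 && stats::var(sex[ctrl]) == 0) {
    stop("singular design: age and sex constant in controls")
  }
  mu_age <- mean(age[ctrl]); mu_sex <- mean(sex[ctrl])
  out <- m
  fits <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    fit <- stats::lm(m[ctrl, j] ~ age[ctrl] + sex[ctrl])
    b <- stats::coef(fit)
    if (anyNA(b)) stop("singular design in control regression")
    adj <- m[, j] - b[2] * (age - mu_age) - b[3] * (sex - mu_sex)
    out[, j] <- ifelse(case == 1, adj, m[, j])
    fits[[j]] <- b
  }
  if (vec_in) out <- drop(out)
  attr(out, "fits") <- fits
  out
}

#' Score the childhood trauma questionnaire
#'
#' Sums 25 Likert items (1-5). Missing items are prorated by the person's
#' mean over observed items (`total = 25 * mean(items)`); persons missing
#' more than `max_missing` of items get `NA`. Totals are clamped to
#' `[25, 125]` and categorized by configurable total-score cut-points.
#'
#' @param items n × 25 matrix (or a single length-25 vector) of item values
#'   in 1..5, `NA` allowed.
#' @param cutpoints Length-2 increasing totals: `none` is `total <=
#'   cutpoints[1]`, `mild` is `(cutpoints[1], cutpoints[2]]`,
#'   `moderate_severe` above. The study's exact category definition comes
#'   from a prior publication on the same sample, so the cut-points are
#'   exposed as configuration.
#' @param max_missing Maximum tolerated fraction of missing items.
#' @return data.frame with `ctq_total` and factor `ct_category`.
#' @export
ctq_score <- function(items, cutpoints = c(31, 51), max_missing = 0.1) {
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  stopifnot(ncol(items) == 25,
            all(items %in% 1:5 | is.na(items)),
            length(cutpoints) == 2, diff(cutpoints) > 0)
  frac_na <- rowMeans(is.na(items))
  total <- 25 * rowMeans(items, na.rm = TRUE)
  total[frac_na > max_missing] <- NA_real_
  total <- pmin(pmax(total, 25), 125)
  cat_lvl <- c("none", "mild", "moderate_severe")
  category <- cut(total, breaks = c(-Inf, cutpoints, Inf), labels = cat_lvl)
  data.frame(ctq_total = total,
             ct_category = factor(category, levels = cat_lvl))
}
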