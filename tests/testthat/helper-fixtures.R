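# Shared fixtures and independent oracles.

# Hand-built genotype panel from an explicit dosage matrix.
make_panel <- function(dosages, a1 = NULL, a2 = NULL, bp = NULL, chr = 1L) {
  m <- ncol(dosages)
  ids <- if (is.null(colnames(dosages))) sprintf("snp%02d", seq_len(m)) else
    colnames(dosages)
  colnames(dosages) <- ids
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("G", m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  meta <- data.frame(id = ids, chr = chr, bp = bp, a1 = a1, a2 = a2,
                     freq = colMeans(dosages, na.rm = TRUE) / 2,
                     stringsAsFactors = FALSE)
  samples <- sprintf("S%03d", seq_len(nrow(dosages)))
  rownames(dosages) <- samples
  structure(list(sample_ids = samples, snp_meta = meta, dosages = dosages),
            class = "genotype_panel")
}

make_sumstats <- function(ids, p, log_or = NULL, chr = 1L, bp = NULL,
                          a1 = "A", a2 = "G") {
  m <- length(ids)
  if (is.null(log_or)) log_or <- rep(0.1, m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  out <- data.frame(id = ids, chr = chr, bp = bp,
                    a1 = rep_len(a1, m), a2 = rep_len(a2, m),
                    or = exp(log_or), log_or = log_or, p = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

# Independent brute-force reference of the greedy clumping rules: explicit
# loops, no shared code with the package implementation.
clump_reference <- function(sumstats, panel, p1 = 0.5, p2 = 0.1,
                            r2_max = 0.25, kb = 300) {
  ss <- as.data.frame(sumstats)
  ss <- ss[ss$id %in% panel$snp_meta$id & !is.na(ss$p), , drop = FALSE]
  status <- rep("free", nrow(ss))  # free | index | removed
  repeat {
    cand <- which(status == "free" & ss$p < p1)
    if (length(cand) == 0) break
    ord <- cand[order(ss$p[cand], ss$chr[cand], ss$bp[cand], ss$id[cand])]
    i <- ord[1]
    status[i] <- "index"
    for (j in seq_len(nrow(ss))) {
      if (status[j] != "free") next
      if (ss$chr[j] != ss$chr[i]) next
      if (abs(ss$bp[j] - ss$bp[i]) > kb * 1000) next
      if (is.na(ss$p[j]) || ss$p[j] >= p2) next
      x <- panel$dosages[, ss$id[i]]
      y <- panel$dosages[, ss$id[j]]
      ok <- !is.na(x) & !is.na(y)
      if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) next
      if (stats::cor(x[ok], y[ok])^2 > r2_max) status[j] <- "removed"
    }
  }
  sort(ss$id[status != "removed"])
}

# Random small clumping instance: blocky LD, random p-values.
random_clump_instance <- function(n_snps = NULL, n = 60) {
  if (is.null(n_snps)) n_snps <- sample(3:20, 1)
  cfg <- simulation_config(n_cases = 10, n_controls = 10, n_snps = n_snps,
                           n_blocks = max(1, n_snps %/% 4),
                           within_block_r = stats::runif(1, 0.3, 0.9),
                           n_causal = 1, seed = sample.int(1e6, 1))
  panel <- simulate_genotypes(cfg, n = n, seed = sample.int(1e6, 1))
  # compress positions so some pairs fall inside / outside the window
  panel$snp_meta$bp <- sort(sample.int(900000L, n_snps))
  ss <- make_sumstats(panel$snp_meta$id, p = stats::runif(n_snps),
                      bp = panel$snp_meta$bp)
  list(panel = panel, sumstats = ss)
}

# Direct evaluation of the Nagelkerke formula, kept separate from the
# package implementation.
nagelkerke_direct <- function(ll_full, ll_null, n) {
  (1 - exp(-2 * (ll_full - ll_null) / n)) / (1 - exp(2 * ll_null / n))
}

# Quick (y, g, e) case-control draw under the logistic disease model, for
# calibration tests that do not need a genotype panel.
draw_gxe_cohort <- function(n_cases, n_controls, or_g = 1.22, or_e = 1.82,
                            or_gxe = 1, prev_e = 0.45,
                            b0 = stats::qlogis(0.10), mult = 15) {
  n_pop <- mult * (n_cases + n_controls)
  g <- stats::rnorm(n_pop)
  e <- stats::rbinom(n_pop, 1, prev_e)
  eta <- b0 + log(or_g) * g + log(or_e) * e + log(or_gxe) * g * e
  y <- stats::rbinom(n_pop, 1, stats::plogis(eta))
  idx <- c(sample(which(y == 1), n_cases), sample(which(y == 0), n_controls))
  list(y = y[idx], g = g[idx], e = e[idx])
}
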