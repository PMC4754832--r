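#' Clumping parameters
#'
#' Parameters of p-value-informed greedy LD clumping, following the PLINK
#' `--clump` convention: `p1` bounds which SNPs may index a clump, `p2`
#' bounds which SNPs may be removed as clump members, `r2` is the LD
#' threshold and `kb` the physical window half-width.
#'
#' @param p1 Index-eligibility p-value threshold.
#' @param p2 Clump-membership p-value threshold (`p2 <= p1`).
#' @param r2 LD threshold: members must have squared dosage correlation
#'   strictly greater than this with their index.
#' @param kb Window in kilobases: members lie within `kb * 1000` bp of the
#'   index on the same chromosome.
#' @return A `clump_params` list.
#' @export
clump_params <- function(p1 = 0.5, p2 = 0.1, r2 = 0.25, kb = 300) {
  stopifnot(p2 > 0, p2 <= p1, p1 <= 1, r2 > 0, r2 < 1, kb > 0)
  structure(list(p1 = p1, p2 = p2, r2 = r2, kb = kb), class = "clump_params")
}

#' Default p-value threshold grid
#'
#' The nine increasingly liberal thresholds used to select clumped SNPs into
#' polygenic scores.
#'
#' @param p_t Strictly increasing thresholds in `(0, 1]`.
#' @return Numeric vector of thresholds.
#' @export
threshold_grid <- function(p_t = c(0.0001, 0.001, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  stopifnot(all(p_t > 0), all(p_t <= 1), all(diff(p_t) > 0))
  p_t
}

#' Squared dosage correlation between two panel SNPs
#'
#' Pearson correlation of dosages over pairwise-complete samples, squared.
#' A monomorphic SNP (zero variance) cannot evidence LD: its r² with
#' anything is defined as 0, with a warning.
#'
#' @param panel A `genotype_panel`.
#' @param snp_a,snp_b SNP ids.
#' @return r² in `[0, 1]`.
#' @export
compute_ld_r2 <- function(panel, snp_a, snp_b) {
  x <- panel$dosages[, snp_a]
  y <- panel$dosages[, snp_b]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete samples")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero dosage variance; r^2 defined as 0")
    return(0)
  }
  stats::cor(x, y)^2
}

#' Greedy p-value-informed LD clumping
#'
#' Sorts SNPs with `p < p1` by ascending p-value (ties broken by chromosome,
#' position, then id) and repeatedly takes the best unassigned SNP as a clump
#' index, removing as members every unassigned SNP with `p < p2` on the same
#' chromosome within the window whose r² with the index exceeds `r2`. SNPs
#' with `p2 <= p < p1` may index a clump but are never removed by a stronger
#' index; SNPs with `p >= p1` pass through untouched. Summary-statistic SNPs
#' absent from the panel cannot be indexed or clumped and are dropped with a
#' logged count.
#'
#' @param sumstats A `summary_stats` data.frame (`id`, `chr`, `bp`, `p`).
#' @param panel A `genotype_panel` providing the LD structure.
#' @param params A [clump_params()].
#' @param index_only If `TRUE`, `retained` holds clump indexes only;
#'   otherwise (default, PLINK-like) it holds every SNP not removed as a
#'   member, including never-clumpable SNPs.
#' @return A `clump_index`: list with `retained` (ids, genomic order),
#'   `index_snps`, `members` (named list index id -> removed member ids),
#'   and `n_not_in_panel`.
#' @export
clump <- function(sumstats, panel, params = clump_params(),
                  index_only = FALSE) {
  ss <- as.data.frame(sumstats)[, c("id", "chr", "bp", "p")]
  ss <- ss[!is.na(ss$p), , drop = FALSE]
  in_panel <- ss$id %in% panel$snp_meta$id
  n_out <- sum(!in_panel)
  if (n_out > 0) {
    message(n_out, " summary-statistic SNP(s) absent from the panel; dropped")
  }
  ss <- ss[in_panel, , drop = FALSE]
  if (nrow(ss) == 0) {
    return(structure(list(retained = character(0), index_snps = character(0),
                          members = list(), n_not_in_panel = n_out),
                     class = "clump_index"))
  }
  ord <- order(ss$chr, ss$bp, ss$id)
  ss <- ss[ord, , drop = FALSE]

  dos <- panel$dosages[, ss$id, drop = FALSE]
  removed <- logical(nrow(ss))
  indexed <- logical(nrow(ss))
  members <- list()

  eligible <- which(ss$p < params$p1)
  eligible <- eligible[order(ss$p[eligible], ss$chr[eligible],
                             ss$bp[eligible], ss$id[eligible])]
  window <- params$kb * 1000
  for (i in eligible) {
    if (removed[i] || indexed[i]) next
    indexed[i] <- TRUE
    cand <- which(!removed & !indexed & ss$chr == ss$chr[i] &
                    abs(ss$bp - ss$bp[i]) <= window & ss$p < params$p2)
    if (length(cand) > 0) {
      x <- dos[, i]
      r2 <- vapply(cand, function(j) {
        y <- dos[, j]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2) return(0)
        if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) return(0)
        stats::cor(x[ok], y[ok])^2
      }, numeric(1))
      hit <- cand[r2 > params$r2]
      removed[hit] <- TRUE
      if (length(hit) > 0) members[[ss$id[i]]] <- ss$id[hit]
    }
  }
  retained <- if (index_only) ss$id[indexed] else ss$id[!removed]
  structure(list(retained = retained, index_snps = ss$id[indexed],
                 members = members, n_not_in_panel = n_out),
            class = "clump_index")
}

#' @export
print.clump_index <- function(x, ...) {
  cat("clump_index:", length(x$index_snps), "index SNPs,",
      length(x$retained), "retained,",
      sum(lengths(x$members)), "removed as members\n")
  invisible(x)
}

#' Select retained SNPs below a p-value threshold
#'
#' @param sumstats Summary statistics restricted to retained SNPs (or full;
#'   supply `retained` to restrict).
#' @param p_t Threshold in `(0, 1]`; SNPs with `p < p_t` are selected.
#' @param retained Optional character vector of retained ids to intersect.
#' @return Character vector of SNP ids.
#' @export
select_threshold_subset <- function(sumstats, p_t, retained = NULL) {
  stopifnot(p_t > 0, p_t <= 1)
  ss <- as.data.frame(sumstats)
  if (!is.null(retained)) ss <- ss[ss$id %in% retained, , drop = FALSE]
  ss$id[!is.na(ss$p) & ss$p < p_t]
}
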