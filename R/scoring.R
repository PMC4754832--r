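#' Harmonize effect alleles between summary statistics and a panel
#'
#' Aligns each summary-statistic SNP's log odds ratio to the allele counted
#' by the panel. Allele pairs equal to the panel's are `matched`; swapped
#' pairs are `flipped` (sign negated); pairs matching after base
#' complementation are `strand_flipped` (sign kept or negated as the
#' complemented pair is direct or swapped); A/T and C/G SNPs are
#' `ambiguous_dropped` because strand cannot be resolved; anything else is
#' `mismatched_dropped`.
#'
#' @param sumstats `summary_stats` data.frame with `id`, `a1`, `a2`,
#'   `log_or`.
#' @param panel A `genotype_panel`.
#' @return `harmonized_weights` data.frame: `id`, `log_or` (aligned; `NA`
#'   for dropped SNPs), `status`. Status counts are attached as attribute
#'   `counts` and reported via `message()`.
#' @export
align_alleles <- function(sumstats, panel) {
  ss <- as.data.frame(sumstats)
  if (anyDuplicated(ss$id)) {
    stop("duplicate SNP ids in summary statistics: ",
         paste(unique(ss$id[duplicated(ss$id)]), collapse = ", "))
  }
  pm <- panel$snp_meta
  if (anyDuplicated(pm$id)) {
    stop("duplicate SNP ids in panel: ",
         paste(unique(pm$id[duplicated(pm$id)]), collapse = ", "))
  }
  common <- intersect(ss$id, pm$id)
  ss <- ss[match(common, ss$id), , drop = FALSE]
  pm <- pm[match(common, pm$id), , drop = FALSE]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  s1 <- toupper(ss$a1); s2 <- toupper(ss$a2)
  p1 <- toupper(pm$a1); p2 <- toupper(pm$a2)
  c1 <- unname(comp[s1]); c2 <- unname(comp[s2])

  status <- rep("mismatched_dropped", length(common))
  status[s1 == p1 & s2 == p2] <- "matched"
  status[s1 == p2 & s2 == p1] <- "flipped"
  status[c1 == p1 & c2 == p2 & !(s1 == p1 & s2 == p2)] <- "strand_flipped"
  status[c1 == p2 & c2 == p1 & !(s1 == p2 & s2 == p1)] <- "strand_flipped_swap"
  status[s1 == c2] <- "ambiguous_dropped"  # A/T or C/G: takes precedence

  sign <- ifelse(status %in% c("matched", "strand_flipped"), 1,
                 ifelse(status %in% c("flipped", "strand_flipped_swap"), -1, NA))
  status[status == "strand_flipped_swap"] <- "strand_flipped"
  out <- data.frame(id = common, log_or = sign * ss$log_or, status = status,
                    stringsAsFactors = FALSE)
  counts <- table(factor(status, levels = c("matched", "flipped",
                                            "strand_flipped",
                                            "ambiguous_dropped",
                                            "mismatched_dropped")))
  attr(out, "counts") <- counts
  message("allele harmonization: ",
          paste(names(counts), as.integer(counts), sep = "=", collapse = ", "))
  class(out) <- c("harmonized_weights", "data.frame")
  out
}

#' Compute a raw polygenic score
#'
#' Per-sample weighted sum of counted-allele dosages,
#' `score_i = sum_j dosage_ij * log_or_j`, over the requested SNP set.
#' Missing dosages are mean-imputed as twice the panel allele frequency
#' (computed from the panel's observed dosages).
#'
#' @param panel A `genotype_panel`.
#' @param weights A `harmonized_weights` data.frame.
#' @param snp_set SNP ids to score; must be a subset of the aligned
#'   (non-dropped) SNPs. An empty set yields all-zero scores with a warning.
#' @return Named numeric vector of raw scores.
#' @export
compute_prs <- function(panel, weights, snp_set) {
  if (length(snp_set) == 0) {
    warning("empty SNP set: scores are all zero")
    return(stats::setNames(numeric(length(panel$sample_ids)),
                           panel$sample_ids))
  }
  w <- weights[match(snp_set, weights$id), , drop = FALSE]
  if (anyNA(w$id) || anyNA(w$log_or)) {
    bad <- snp_set[is.na(w$id) | is.na(w$log_or)]
    stop("SNPs not among aligned weights: ", paste(bad, collapse = ", "))
  }
  m <- panel$dosages[, snp_set, drop = FALSE]
  if (anyNA(m)) {
    freq <- colMeans(m, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(m)) > 0)) {
      fill <- if (is.nan(freq[j])) 2 * panel$snp_meta$freq[
        match(snp_set[j], panel$snp_meta$id)] else 2 * freq[j]
      m[is.na(m[, j]), j] <- fill
    }
  }
  stats::setNames(as.vector(m %*% w$log_or), panel$sample_ids)
}

#' Score a panel over a p-value threshold grid
#'
#' Computes one raw polygenic score per threshold (SNPs with `p < p_T` among
#' the retained, aligned set) and standardizes each column to mean 0, SD 1
#' over all scored samples.
#'
#' @param panel A `genotype_panel`.
#' @param weights A `harmonized_weights` data.frame.
#' @param sumstats Summary statistics carrying the per-SNP p-values.
#' @param grid Threshold grid from [threshold_grid()].
#' @param retained Optional ids restricting the scoring set (e.g. clump
#'   output).
#' @return A `score_matrix`: list with `raw` and `std` (n × length(grid)
#'   matrices, columns named `pT_<value>`), `n_snps` per threshold, `grid`.
#'   Thresholds with zero SNPs give zero columns and are flagged in
#'   `empty_thresholds`.
#' @export
score_grid <- function(panel, weights, sumstats, grid = threshold_grid(),
                       retained = NULL) {
  aligned <- weights$id[!is.na(weights$log_or)]
  ss <- as.data.frame(sumstats)
  ss <- ss[ss$id %in% aligned, , drop = FALSE]
  if (!is.null(retained)) ss <- ss[ss$id %in% retained, , drop = FALSE]
  n <- length(panel$sample_ids)
  raw <- matrix(0, n, length(grid),
                dimnames = list(panel$sample_ids, paste0("pT_", grid)))
  n_snps <- integer(length(grid))
  for (k in seq_along(grid)) {
    ids <- ss$id[!is.na(ss$p) & ss$p < grid[k]]
    n_snps[k] <- length(ids)
    if (length(ids) > 0) raw[, k] <- compute_prs(panel, weights, ids)
  }
  std <- raw
  for (k in seq_along(grid)) {
    s <- stats::sd(raw[, k])
    std[, k] <- if (s > 0) (raw[, k] - mean(raw[, k])) / s else 0
  }
  empty <- grid[n_snps == 0]
  if (length(empty) > 0) {
    warning("thresholds with zero SNPs: ", paste(empty, collapse = ", "))
  }
  structure(list(raw = raw, std = std, n_snps = n_snps, grid = grid,
                 empty_thresholds = empty),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix:", nrow(x$raw), "samples x", length(x$grid),
      "thresholds; SNPs per threshold:",
      paste(x$n_snps, collapse = ", "), "\n")
  invisible(x)
}
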