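#' Write a table as TSV with a commented metadata header
#'
#' All pipeline tables are tab-separated with `#`-prefixed metadata lines
#' (key: value) before the column header; missing values are written as
#' `NA`.
#'
#' @param x data.frame.
#' @param path Output path.
#' @param meta Named character/numeric vector of metadata to record.
#' @export
write_tsv_meta <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path Input path.
#' @return data.frame; `#` metadata lines are returned in attribute `meta`.
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  out <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           na.strings = "NA", stringsAsFactors = FALSE,
                           check.names = FALSE)
  attr(out, "meta") <- sub("^# ", "", meta)
  out
}

#' Write summary statistics in daner-style format
#'
#' Whitespace-delimited columns `SNP CHR BP A1 A2 OR P`.
#'
#' @param sumstats `summary_stats` data.frame.
#' @param path Output path.
#' @export
write_daner <- function(sumstats, path) {
  out <- data.frame(SNP = sumstats$id, CHR = sumstats$chr, BP = sumstats$bp,
                    A1 = sumstats$a1, A2 = sumstats$a2,
                    OR = sumstats$or, P = sumstats$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read daner-style summary statistics
#'
#' @param path Input path (whitespace/tab-delimited, columns
#'   `SNP CHR BP A1 A2 OR P`).
#' @return `summary_stats` data.frame with `log_or` derived from `OR`.
#' @export
read_daner <- function(path) {
  x <- utils::read.table(path, header = TRUE, na.strings = "NA",
                         stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "OR", "P")
  if (!all(need %in% names(x))) {
    stop("missing daner columns: ", paste(setdiff(need, names(x)),
                                          collapse = ", "))
  }
  out <- data.frame(id = x$SNP, chr = x$CHR, bp = x$BP,
                    a1 = toupper(x$A1), a2 = toupper(x$A2),
                    or = x$OR, log_or = log(x$OR), p = x$P,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write a genotype panel as PLINK-raw-style dosage text
#'
#' Columns `FID IID` then one dosage column per SNP named `<id>_<A1>`.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @export
write_dosage_raw <- function(panel, path) {
  d <- as.data.frame(panel$dosages)
  names(d) <- paste0(panel$snp_meta$id, "_", panel$snp_meta$a1)
  out <- cbind(FID = panel$sample_ids, IID = panel$sample_ids, d)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write bim-style SNP metadata
#'
#' Columns: chromosome, id, genetic distance (0), bp, A1, A2.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @export
write_bim <- function(panel, path) {
  m <- panel$snp_meta
  out <- data.frame(m$chr, m$id, 0, m$bp, m$a1, m$a2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix and bim metadata back into a genotype panel
#'
#' @param raw_path PLINK-raw-style dosage text from [write_dosage_raw()].
#' @param bim_path bim-style metadata from [write_bim()].
#' @param freq Optional per-SNP A1 frequencies; recomputed from dosages when
#'   absent.
#' @return A `genotype_panel`.
#' @export
read_dosage_raw <- function(raw_path, bim_path, freq = NULL) {
  x <- utils::read.table(raw_path, header = TRUE, na.strings = "NA",
                         stringsAsFactors = FALSE, check.names = FALSE)
  bim <- utils::read.table(bim_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "id", "cm", "bp", "a1", "a2"))
  dos <- as.matrix(x[, -(1:2), drop = FALSE])
  got <- sub("_[ACGT]$", "", colnames(dos))
  if (!identical(got, bim$id)) stop("dosage columns do not match bim ids")
  colnames(dos) <- bim$id
  rownames(dos) <- x$IID
  if (is.null(freq)) freq <- colMeans(dos, na.rm = TRUE) / 2
  meta <- data.frame(id = bim$id, chr = bim$chr, bp = bim$bp,
                     a1 = bim$a1, a2 = bim$a2, freq = unname(freq),
                     stringsAsFactors = FALSE)
  structure(list(sample_ids = x$IID, snp_meta = meta, dosages = dos),
            class = "genotype_panel")
}
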