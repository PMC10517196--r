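SUMSTAT_COLS <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "P")

#' Read GWAS summary statistics
#'
#' Tab-delimited with header columns SNP, CHR, BP, A1, A2, BETA, P and an
#' optional MAF column. A1 is the effect allele; BETA is the per-A1-allele
#' effect (log odds for case-control GWAS — odds ratios must be
#' log-transformed upstream). Rows failing validation (P outside (0, 1],
#' non-SNP or identical alleles, bp < 1, unparseable numbers) are rejected
#' and reported with their row numbers; nothing is dropped silently.
#'
#' @param path path to the summary-statistics file.
#' @return A data.frame with columns `variant_id`, `chrom`, `bp`, `a1`,
#'   `a2`, `beta`, `p` (and `maf` if present), one row per accepted record.
#'   Attributes `n_accepted`, `n_rejected` and `rejected` (data.frame of
#'   row numbers and reasons) carry the validation report.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  miss <- setdiff(SUMSTAT_COLS, names(raw))
  if (length(miss))
    stop("summary-statistics header lacks required column(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(raw)
  bp <- suppressWarnings(as.integer(raw$BP))
  beta <- suppressWarnings(as.numeric(raw$BETA))
  p <- suppressWarnings(as.numeric(raw$P))
  a1 <- toupper(raw$A1); a2 <- toupper(raw$A2)
  snp_alleles <- c("A", "C", "G", "T")
  reason <- character(n)
  bad <- function(cond, why) {
    hit <- which(cond & reason == "")
    reason[hit] <<- why
  }
  bad(is.na(beta), "unparseable BETA")
  bad(is.na(p), "unparseable P")
  bad(!is.na(p) & (p <= 0 | p > 1), "P outside (0, 1]")
  bad(is.na(bp) | bp < 1, "invalid BP")
  bad(!(a1 %in% snp_alleles) | !(a2 %in% snp_alleles), "non-SNP allele")
  bad(a1 == a2, "identical alleles")
  keep <- reason == ""
  out <- data.frame(variant_id = raw$SNP[keep], chrom = raw$CHR[keep],
                    bp = bp[keep], a1 = a1[keep], a2 = a2[keep],
                    beta = beta[keep], p = p[keep],
                    stringsAsFactors = FALSE)
  if ("MAF" %in% names(raw)) {
    maf <- suppressWarnings(as.numeric(raw$MAF))
    out$maf <- maf[keep]
  }
  rejected <- data.frame(row = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    warning(sprintf("rejected %d of %d summary-stat rows (e.g. row %d: %s)",
                    nrow(rejected), n, rejected$row[1], rejected$reason[1]))
  attr(out, "n_accepted") <- sum(keep)
  attr(out, "n_rejected") <- nrow(rejected)
  attr(out, "rejected") <- rejected
  out
}

#' Write summary statistics in the canonical schema
#'
#' @param stats data.frame as returned by [read_summary_stats()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  out <- data.frame(SNP = stats$variant_id, CHR = stats$chrom,
                    BP = stats$bp, A1 = stats$a1, A2 = stats$a2,
                    BETA = stats$beta, P = stats$p)
  if (!is.null(stats$maf)) out$MAF <- stats$maf
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
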