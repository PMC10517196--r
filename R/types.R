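#' Construct a genotype matrix object
#'
#' The central genotype container: a samples x variants dosage matrix in
#' \[0, 2\] (alt-allele count or imputed dosage, NA = missing) plus a variant
#' annotation table. Variants are stored sorted by (chrom, bp); unsorted
#' input is sorted with a message.
#'
#' @param dosage numeric matrix, rows = samples, columns = variants.
#' @param sample_ids character vector of unique sample identifiers.
#' @param variants data.frame with columns `variant_id`, `chrom`, `bp`,
#'   `ref`, `alt` (one row per dosage column).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sample_ids`, `variants`, `dosage`.
#' @export
genotype_matrix <- function(dosage, sample_ids, variants) {
  dosage <- as.matrix(dosage)
  stopifnot(is.numeric(dosage) || all(is.na(dosage)))
  storage.mode(dosage) <- "double"
  if (length(sample_ids) != nrow(dosage))
    stop("sample_ids length does not match dosage rows")
  if (nrow(variants) != ncol(dosage))
    stop("variants rows do not match dosage columns")
  req <- c("variant_id", "chrom", "bp", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop("variants table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs")
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant IDs")
  if (length(dosage) && !all(is.na(dosage))) {
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosage values outside [0, 2]")
  }
  variants <- as.data.frame(variants)[, req]
  variants$chrom <- as.character(variants$chrom)
  variants$bp <- as.integer(variants$bp)
  ord <- order(variants$chrom, variants$bp)
  if (is.unsorted(ord)) {
    message("variants not sorted by (chrom, bp); sorting")
    variants <- variants[ord, , drop = FALSE]
    dosage <- dosage[, ord, drop = FALSE]
  }
  rownames(variants) <- NULL
  dimnames(dosage) <- list(sample_ids, variants$variant_id)
  structure(list(sample_ids = as.character(sample_ids),
                 variants = variants,
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              length(x$sample_ids), nrow(x$variants),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Genomic region (1-based, closed interval)
#'
#' Used for the APOE locus (chr19:44,400,000-46,500,000 by default) when
#' building scores with, without, or only that region.
#'
#' @param chrom chromosome name.
#' @param start_bp,end_bp closed interval bounds, `start_bp <= end_bp`.
#' @return A `region_spec` list.
#' @export
region_spec <- function(chrom = "19", start_bp = 44400000L,
                        end_bp = 46500000L) {
  start_bp <- as.integer(start_bp); end_bp <- as.integer(end_bp)
  if (start_bp > end_bp) stop("start_bp must be <= end_bp")
  structure(list(chrom = as.character(chrom), start_bp = start_bp,
                 end_bp = end_bp), class = "region_spec")
}

#' Clumping and thresholding parameters
#'
#' Defaults follow the standard clumping-and-thresholding protocol:
#' index SNPs chosen greedily by ascending P, neighbours within 500 kb at
#' r-squared > 0.2 removed, and scores built at a ladder of P-value
#' thresholds (0.5, 0.3, 0.1, 0.01, 1e-4, 1e-6, 1e-7) with 0.001 as the
#' primary threshold.
#'
#' @param r2_max r-squared above which a neighbour is clumped away (0, 1).
#' @param window_kb clumping window in kilobases (hard bound, both sides).
#' @param p_thresholds numeric vector of P-value thresholds, sorted
#'   decreasing.
#' @param primary_threshold the threshold used for primary analyses.
#' @return A `clump_spec` list.
#' @export
clump_spec <- function(r2_max = 0.2, window_kb = 500,
                       p_thresholds = c(0.5, 0.3, 0.1, 0.01, 0.001,
                                        1e-4, 1e-6, 1e-7),
                       primary_threshold = 0.001) {
  if (r2_max <= 0 || r2_max >= 1) stop("r2_max must be in (0, 1)")
  if (window_kb <= 0) stop("window_kb must be > 0")
  if (is.unsorted(rev(p_thresholds), strictly = TRUE))
    stop("p_thresholds must be sorted strictly decreasing")
  if (!primary_threshold %in% p_thresholds)
    p_thresholds <- sort(c(p_thresholds, primary_threshold),
                         decreasing = TRUE)
  structure(list(r2_max = r2_max, window_kb = window_kb,
                 p_thresholds = p_thresholds,
                 primary_threshold = primary_threshold),
            class = "clump_spec")
}

#' Quality-control thresholds
#'
#' Defaults mirror common array-QC practice: variants are dropped at minor
#' allele frequency < 1%, SNP call rate < 98% or Hardy-Weinberg equilibrium
#' P < 1e-4; samples at < 97% genotyping completeness; ROI values more than
#' 2.5 SD from the ROI mean are set missing.
#'
#' @param maf_min minimum minor allele frequency.
#' @param variant_call_min minimum per-variant call rate.
#' @param sample_call_min minimum per-sample completeness.
#' @param hwe_p_min minimum HWE exact chi-square P-value.
#' @param roi_outlier_sd ROI outlier cut in standard deviations.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.01, variant_call_min = 0.98,
                          sample_call_min = 0.97, hwe_p_min = 1e-4,
                          roi_outlier_sd = 2.5) {
  for (v in c(maf_min, variant_call_min, sample_call_min, hwe_p_min))
    if (v <= 0 || v > 1) stop("QC probability thresholds must lie in (0, 1]")
  if (roi_outlier_sd <= 0) stop("roi_outlier_sd must be > 0")
  structure(list(maf_min = maf_min, variant_call_min = variant_call_min,
                 sample_call_min = sample_call_min, hwe_p_min = hwe_p_min,
                 roi_outlier_sd = roi_outlier_sd),
            class = "qc_thresholds")
}
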