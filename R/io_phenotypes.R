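ASSOC_COLS <- c("roi", "score_label", "threshold", "apoe_mode", "n", "beta",
                "se", "ci_low", "ci_high", "p", "q", "delta_r2_prs",
                "delta_r2_apoe", "beats_apoe")

#' Read a phenotype/covariate table
#'
#' Tab-delimited with a `sample_id` column, one column per ROI measure
#' (cortical thickness in mm, subcortical volume in mm^3) and one per
#' covariate (age, sex, ICV, site, array, ancestry PCs). Declared ROI and
#' covariate columns must be present; non-numeric ROI cells become missing
#' with a warning.
#'
#' @param path input TSV.
#' @param roi_cols character vector of ROI column names expected.
#' @param covariate_cols character vector of covariate column names expected.
#' @return A data.frame with attributes `roi_cols` and `covariate_cols`.
#' @export
read_phenotype_table <- function(path, roi_cols, covariate_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stop("phenotype table lacks sample_id")
  if (anyDuplicated(tab$sample_id))
    stop("duplicated sample_id in phenotype table")
  miss <- setdiff(c(roi_cols, covariate_cols), names(tab))
  if (length(miss))
    stop("phenotype table missing declared column(s): ",
         paste(miss, collapse = ", "))
  tab$sample_id <- as.character(tab$sample_id)
  for (rc in roi_cols) {
    v <- suppressWarnings(as.numeric(tab[[rc]]))
    turned <- sum(is.na(v) & !is.na(tab[[rc]]) & tab[[rc]] != "NA")
    if (turned > 0)
      warning(sprintf("%d non-numeric value(s) in ROI '%s' set missing",
                      turned, rc))
    tab[[rc]] <- v
  }
  attr(tab, "roi_cols") <- roi_cols
  attr(tab, "covariate_cols") <- covariate_cols
  tab
}

#' Write a phenotype table
#'
#' @param ph data.frame with `sample_id` plus ROI/covariate columns.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(ph, path) {
  utils::write.table(ph, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the association results table
#'
#' Fixed column set and order: roi, score_label, threshold, apoe_mode, n,
#' beta, se, ci_low, ci_high, p, q, delta_r2_prs, delta_r2_apoe,
#' beats_apoe.
#'
#' @param res association results data.frame.
#' @param path TSV path.
#' @return `path` invisibly (write); the data.frame (read).
#' @export
write_association_table <- function(res, path) {
  miss <- setdiff(ASSOC_COLS, names(res))
  if (length(miss))
    stop("association table missing column(s): ", paste(miss, collapse = ", "))
  utils::write.table(res[, ASSOC_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(tab), ASSOC_COLS))
    stop("association table columns differ from the fixed schema")
  tab$beats_apoe <- as.logical(tab$beats_apoe)
  tab
}
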