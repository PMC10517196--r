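#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit chi-square of observed genotype
#' counts against the proportions p^2, 2pq, q^2 expected from the observed
#' allele frequency. Monomorphic sites (one allele absent) have no HWE
#' deviation to test; they return p = 1 with a flag.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts (reference
#'   homozygote, heterozygote, alternate homozygote).
#' @return list with `chisq`, `p`, `monomorphic`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype count")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0)
    return(list(chisq = 0, p = 1, monomorphic = TRUE))
  expd <- n * c(p^2, 2 * p * q, q^2)
  chisq <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Remove samples with low genotyping completeness
#'
#' Drops samples whose non-missing dosage fraction is below
#' `t$sample_call_min` (default 0.97).
#'
#' @param G a [genotype_matrix()].
#' @param t [qc_thresholds()].
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (data.frame sample_id, completeness, removed).
#' @export
filter_samples <- function(G, t = qc_thresholds()) {
  comp <- rowMeans(!is.na(G$dosage))
  removed <- comp < t$sample_call_min
  if (all(removed)) stop("all samples fail the completeness filter")
  report <- data.frame(sample_id = G$sample_ids, completeness = comp,
                       removed = removed, stringsAsFactors = FALSE)
  out <- genotype_matrix(G$dosage[!removed, , drop = FALSE],
                         G$sample_ids[!removed], G$variants)
  list(genotypes = out, report = report)
}

hard_calls <- function(d) {
  # HWE and hard-call QC operate on rounded genotypes; scores keep dosages
  pmin(pmax(round(d), 0), 2)
}

#' Variant-level QC: call rate, MAF, Hardy-Weinberg
#'
#' Removes variants failing any of: call rate < `variant_call_min`, minor
#' allele frequency < `maf_min`, HWE chi-square P < `hwe_p_min`. The three
#' predicates are evaluated on the unfiltered matrix, so their order does
#' not change the retained set; the report attributes each removal to the
#' first failing filter in the order call rate, MAF, HWE. HWE is computed
#' on dosages rounded to hard genotype calls.
#'
#' @param G a [genotype_matrix()].
#' @param t [qc_thresholds()].
#' @return list with `genotypes` and `report` (per-variant call_rate, maf,
#'   hwe_p, removed, reason; plus attribute `counts`).
#' @export
filter_variants <- function(G, t = qc_thresholds()) {
  d <- G$dosage
  call_rate <- colMeans(!is.na(d))
  hc <- hard_calls(d)
  af <- colMeans(hc, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  hwe_p <- vapply(seq_len(ncol(hc)), function(j) {
    g <- hc[, j][!is.na(hc[, j])]
    if (!length(g)) return(1)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))$p
  }, numeric(1))
  fail_call <- call_rate < t$variant_call_min
  fail_maf <- maf < t$maf_min
  fail_hwe <- hwe_p < t$hwe_p_min
  removed <- fail_call | fail_maf | fail_hwe
  reason <- rep(NA_character_, ncol(d))
  reason[fail_hwe] <- "hwe"
  reason[fail_maf] <- "maf"
  reason[fail_call] <- "call_rate"
  report <- data.frame(variant_id = G$variants$variant_id,
                       call_rate = call_rate, maf = maf, hwe_p = hwe_p,
                       removed = removed, reason = reason,
                       stringsAsFactors = FALSE)
  attr(report, "counts") <- c(call_rate = sum(fail_call),
                              maf = sum(fail_maf), hwe = sum(fail_hwe),
                              removed = sum(removed))
  if (all(removed)) warning("all variants removed by QC")
  out <- genotype_matrix(d[, !removed, drop = FALSE], G$sample_ids,
                         G$variants[!removed, , drop = FALSE])
  list(genotypes = out, report = report)
}

#' Remove ROI outliers
#'
#' Per ROI, values more than `roi_outlier_sd` (default 2.5) standard
#' deviations from that ROI's mean are set to missing. A single pass: mean
#' and SD come from all non-missing values before any removal, and removal
#' is per-ROI, so a sample outlying on one ROI keeps its other values.
#'
#' @param ph phenotype data.frame (see [read_phenotype_table()]).
#' @param t [qc_thresholds()].
#' @param roi_cols ROI column names; defaults to the table's `roi_cols`
#'   attribute.
#' @return list with `phenotypes` and `report` (per-ROI n_removed and a
#'   zero-variance flag).
#' @export
remove_roi_outliers <- function(ph, t = qc_thresholds(),
                                roi_cols = attr(ph, "roi_cols")) {
  if (is.null(roi_cols)) stop("roi_cols not supplied and not an attribute")
  rep_rows <- lapply(roi_cols, function(rc) {
    v <- ph[[rc]]
    ok <- !is.na(v)
    if (sum(ok) < 3) stop("fewer than 3 non-missing values for ROI ", rc)
    m <- mean(v[ok]); s <- stats::sd(v[ok])
    if (s == 0)
      return(data.frame(roi = rc, n_removed = 0L, zero_variance = TRUE))
    out <- ok & abs(v - m) > t$roi_outlier_sd * s
    ph[[rc]][out] <<- NA
    data.frame(roi = rc, n_removed = sum(out), zero_variance = FALSE)
  })
  list(phenotypes = ph, report = do.call(rbind, rep_rows))
}

#' Ancestry principal components from genotype dosages
#'
#' Missing dosages are mean-imputed per variant, dosages standardized to
#' per-variant mean 0 / unit variance (zero-variance variants dropped), and
#' the leading singular vectors extracted. PCs are ordered by decreasing
#' explained variance and sign-fixed so the largest-magnitude variant
#' loading of each component is positive, making the result deterministic.
#'
#' @param G a [genotype_matrix()].
#' @param k number of components requested; truncated to the matrix rank
#'   with a warning if it exceeds it.
#' @return numeric matrix (samples x k) with rownames = sample IDs and
#'   columns PC1..PCk; attribute `var_explained` holds the variance shares.
#' @export
compute_pcs <- function(G, k) {
  d <- G$dosage
  if (k < 1) stop("k must be >= 1")
  mu <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  sdv <- apply(d, 2, stats::sd)
  keep <- sdv > 0
  X <- scale(d[, keep, drop = FALSE])
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (k > rank) {
    warning(sprintf("k = %d exceeds rank %d; truncating", k, rank))
    k <- rank
  }
  flip <- vapply(seq_len(k), function(i) {
    v <- sv$v[, i]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)] * flip, nrow = k)
  dimnames(scores) <- list(G$sample_ids, paste0("PC", seq_len(k)))
  attr(scores, "var_explained") <- (sv$d[seq_len(k)]^2 / sum(sv$d^2))
  scores
}
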