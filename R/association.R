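#' Covariate-adjusted association of one ROI with one score
#'
#' Ordinary least squares of the ROI measure on \[intercept, score,
#' covariates\] over complete cases, reporting the score coefficient with
#' its standard error, t-based 95% confidence interval and P-value, plus
#' the incremental R-squared of the score over the covariates-only model.
#' A constant score or a rank-deficient design is flagged unestimable
#' rather than silently pseudo-inverted.
#'
#' @param y numeric ROI values.
#' @param s numeric score values.
#' @param X covariate data.frame or matrix (may be NULL / zero columns).
#' @param conf_level confidence level for the interval.
#' @return list with n, beta, se, ci_low, ci_high, p, r2_full, r2_cov,
#'   delta_r2, unestimable.
#' @export
fit_association <- function(y, s, X = NULL, conf_level = 0.95) {
  dat <- data.frame(.y = y, .s = s)
  if (!is.null(X) && NCOL(X) > 0) dat <- cbind(dat, as.data.frame(X))
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  n <- nrow(dat)
  unest <- list(n = n, beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, p = NA_real_, r2_full = NA_real_,
                r2_cov = NA_real_, delta_r2 = NA_real_, unestimable = TRUE)
  if (n < ncol(dat) + 2) return(unest)
  if (stats::sd(dat$.s) == 0) return(unest)
  fit <- stats::lm(.y ~ ., data = dat)
  co <- stats::coef(fit)
  if (anyNA(co)) return(unest)  # collinear design
  sm <- suppressWarnings(summary(fit))
  est <- sm$coefficients[".s", ]
  df <- fit$df.residual
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  cov_fit <- stats::lm(.y ~ . - .s, data = dat)
  r2_full <- sm$r.squared
  r2_cov <- summary(cov_fit)$r.squared
  list(n = n, beta = unname(est["Estimate"]), se = unname(est["Std. Error"]),
       ci_low = unname(est["Estimate"] - tq * est["Std. Error"]),
       ci_high = unname(est["Estimate"] + tq * est["Std. Error"]),
       p = unname(est["Pr(>|t|)"]),
       r2_full = r2_full, r2_cov = r2_cov,
       delta_r2 = max(0, r2_full - r2_cov), unestimable = FALSE)
}

#' Incremental R-squared of a score over covariates
#'
#' delta = R2(y ~ X + s) - R2(y ~ X) on the same complete-case rows.
#'
#' Defined even when the score is collinear with a covariate (the nested
#' fits are then identical and delta is 0), unlike [fit_association()],
#' which flags that design unestimable for its coefficient.
#'
#' @inheritParams fit_association
#' @return list with r2_full, r2_cov, delta.
#' @export
delta_r2 <- function(y, s, X = NULL) {
  dat <- data.frame(.y = y, .s = s)
  if (!is.null(X) && NCOL(X) > 0) dat <- cbind(dat, as.data.frame(X))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  r2_full <- suppressWarnings(
    summary(stats::lm(.y ~ ., data = dat))$r.squared)
  r2_cov <- suppressWarnings(
    summary(stats::lm(.y ~ . - .s, data = dat))$r.squared)
  list(r2_full = r2_full, r2_cov = r2_cov,
       delta = max(0, r2_full - r2_cov))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: with ordered p-values p_(1) <= ... <= p_(m),
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1, mapped back to
#' the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Run the score x ROI association grid
#'
#' Fits every (score column, ROI) pair with covariate adjustment; applies
#' BH-FDR separately within each (ROI family x APOE mode x threshold)
#' block (the "10 scores x n family ROIs" correction scheme; `fdr_scope =
#' "joint"` pools the families instead); and compares each score's
#' incremental R-squared with that of the genome-wide APOE-only score at
#' the same threshold (`beats_apoe`). Scores are z-standardized before
#' fitting by default, so betas are per score-SD; `standardize = FALSE`
#' reproduces raw per-score-unit betas. The `apoe_only` score columns are
#' the comparator, not rows of the grid.
#'
#' @param st a `score_table` from [build_score_matrix()].
#' @param ph phenotype data.frame with `sample_id`, ROI and covariate
#'   columns.
#' @param roi_families named list: family -> character vector of ROI
#'   column names (families must be disjoint).
#' @param covariate_cols covariate column names in `ph`.
#' @param fdr_scope "family" (default) or "joint".
#' @param standardize z-standardize each score column before fitting.
#' @return data.frame in the fixed association-table schema (see
#'   [write_association_table()]), sorted by (family, roi, score_label);
#'   extra columns `family`, `n_snps_used`, `unestimable`.
#' @export
run_association_grid <- function(st, ph, roi_families, covariate_cols,
                                 fdr_scope = c("family", "joint"),
                                 standardize = TRUE) {
  fdr_scope <- match.arg(fdr_scope)
  if (any(duplicated(unlist(roi_families))))
    stop("ROI families must be disjoint")
  meta <- st$meta
  idx <- match(ph$sample_id, st$scores$sample_id)
  if (anyNA(idx)) stop("phenotype samples missing from score table")
  sc <- st$scores[idx, , drop = FALSE]
  X <- ph[, covariate_cols, drop = FALSE]
  apoe_meta <- meta[meta$apoe_mode == "apoe_only" &
                      meta$score_label == "genome_wide", , drop = FALSE]
  test_meta <- meta[meta$apoe_mode != "apoe_only", , drop = FALSE]

  rows <- list()
  for (fam in names(roi_families)) {
    for (roi in roi_families[[fam]]) {
      y <- ph[[roi]]
      if (is.null(y)) stop("ROI column absent from phenotype table: ", roi)
      apoe_delta <- stats::setNames(
        vapply(seq_len(nrow(apoe_meta)), function(i) {
          fit_association(y, sc[[apoe_meta$column[i]]], X)$delta_r2
        }, numeric(1)), as.character(apoe_meta$threshold))
      for (i in seq_len(nrow(test_meta))) {
        s <- sc[[test_meta$column[i]]]
        if (standardize && !all(is.na(s)) && stats::sd(s, na.rm = TRUE) > 0)
          s <- as.numeric(scale(s))
        f <- fit_association(y, s, X)
        da <- unname(apoe_delta[as.character(test_meta$threshold[i])])
        if (!length(da)) da <- NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, roi = roi,
          score_label = test_meta$score_label[i],
          threshold = test_meta$threshold[i],
          apoe_mode = test_meta$apoe_mode[i],
          n = f$n, beta = f$beta, se = f$se, ci_low = f$ci_low,
          ci_high = f$ci_high, p = f$p, q = NA_real_,
          delta_r2_prs = f$delta_r2,
          delta_r2_apoe = da,
          beats_apoe = if (!is.na(f$delta_r2) && !is.na(da))
            f$delta_r2 > da else NA,
          n_snps_used = test_meta$n_snps_used[i],
          unestimable = f$unestimable,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  block <- if (fdr_scope == "family")
    interaction(res$family, res$apoe_mode, res$threshold, drop = TRUE)
  else interaction(res$apoe_mode, res$threshold, drop = TRUE)
  for (b in levels(block)) {
    in_b <- block == b & !res$unestimable & !is.na(res$p)
    if (any(in_b)) res$q[in_b] <- bh_fdr(res$p[in_b])
  }
  res <- res[order(res$family, res$roi, res$score_label, res$apoe_mode,
                   -res$threshold), , drop = FALSE]
  rownames(res) <- NULL
  res
}
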