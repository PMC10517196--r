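#' Harmonize summary-statistic weights to target genotypes
#'
#' Matches discovery records to target variants by (chrom, bp) and allele
#' pair, orienting each effect to the target's alt allele: if the effect
#' allele A1 equals alt (and A2 equals ref) the beta is kept as-is
#' (`same`); if A1 equals ref (and A2 equals alt) the beta is negated
#' (`flipped`). Strand-ambiguous (palindromic A/T, C/G) pairs are dropped,
#' as are allele mismatches; positions with conflicting duplicate records
#' are dropped entirely.
#'
#' @param stats summary statistics (see [read_summary_stats()]).
#' @param G a [genotype_matrix()].
#' @return A data.frame of harmonized weights with columns
#'   `variant_index` (column in `G$dosage`), `variant_id`, `chrom`, `bp`,
#'   `beta_alt`, `p`, `orientation`, `status`; rows with status other than
#'   "ok" carry NA beta_alt. Attribute `counts` reports per-status totals.
#' @export
harmonize_weights <- function(stats, G) {
  v <- G$variants
  key_g <- paste(v$chrom, v$bp, sep = ":")
  key_s <- paste(stats$chrom, stats$bp, sep = ":")
  idx <- match(key_s, key_g)
  hit <- !is.na(idx)
  s <- stats[hit, , drop = FALSE]
  gi <- idx[hit]
  ref <- v$ref[gi]; alt <- v$alt[gi]
  palindromic <- (s$a1 == chartr("ACGT", "TGCA", s$a2))
  same <- s$a1 == alt & s$a2 == ref
  flipped <- s$a1 == ref & s$a2 == alt
  status <- rep("mismatch_dropped", nrow(s))
  status[same | flipped] <- "ok"
  status[palindromic] <- "ambiguous_dropped"
  # duplicate target positions with conflicting alleles: drop all
  dup <- duplicated(gi) | duplicated(gi, fromLast = TRUE)
  if (any(dup & status == "ok")) {
    warning("duplicate position(s) with conflicting records dropped")
    status[dup] <- "mismatch_dropped"
  }
  orientation <- ifelse(same, "same", ifelse(flipped, "flipped", NA))
  orientation[status != "ok"] <- NA
  beta_alt <- ifelse(same, s$beta, -s$beta)
  beta_alt[status != "ok"] <- NA
  out <- data.frame(variant_index = gi, variant_id = v$variant_id[gi],
                    chrom = v$chrom[gi], bp = v$bp[gi],
                    beta_alt = beta_alt, p = s$p,
                    orientation = orientation, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(status, levels = c(
    "ok", "ambiguous_dropped", "mismatch_dropped")))
  out
}

ok_weights <- function(w) w[w$status == "ok", , drop = FALSE]

#' Select weights by discovery P-value threshold
#'
#' Retains ok-status weights with p <= pT (boundary inclusive).
#'
#' @param weights harmonized weights.
#' @param pT threshold in (0, 1].
#' @return subset of `weights`.
#' @export
threshold_by_p <- function(weights, pT) {
  w <- ok_weights(weights)
  out <- w[w$p <= pT, , drop = FALSE]
  if (!nrow(out)) warning("no SNPs pass P-threshold ", pT)
  out
}

#' Restrict weights relative to a genomic region
#'
#' `mode = "exclude"` drops SNPs inside the closed interval (the
#' APOE-excluded score); `mode = "only"` keeps exactly those (the
#' APOE-only score). The two modes partition the input.
#'
#' @param weights harmonized weights.
#' @param region a [region_spec()].
#' @param mode "exclude" or "only".
#' @return subset of `weights`.
#' @export
exclude_region <- function(weights, region, mode = c("exclude", "only")) {
  mode <- match.arg(mode)
  inside <- weights$chrom == region$chrom &
    weights$bp >= region$start_bp & weights$bp <= region$end_bp
  weights[if (mode == "exclude") !inside else inside, , drop = FALSE]
}

#' Restrict weights to a pathway SNP set
#'
#' @param weights harmonized weights.
#' @param ps a `pathway_snp_set` (see [build_pathway_snp_sets()]).
#' @return subset of `weights` whose variant IDs lie in `ps$snp_ids`.
#' @export
restrict_to_pathway <- function(weights, ps) {
  out <- weights[weights$variant_id %in% ps$snp_ids, , drop = FALSE]
  if (!nrow(out))
    warning("no weights overlap pathway ", ps$pathway_id)
  out
}

# r^2 between dosage column i and columns js: squared pairwise-complete
# Pearson correlation; undefined (zero-variance) correlations count as 0.
dosage_r2 <- function(d, i, js) {
  r <- suppressWarnings(
    stats::cor(d[, i], d[, js, drop = FALSE],
               use = "pairwise.complete.obs"))
  r2 <- as.numeric(r)^2
  r2[is.na(r2)] <- 0
  r2
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: repeatedly take the remaining SNP with the
#' smallest P-value (ties broken by smaller bp) as an index SNP, then
#' remove all remaining SNPs on the same chromosome within `window_kb`
#' kilobases whose dosage r-squared with the index exceeds `r2_max`. LD is
#' the squared Pearson correlation of target-cohort dosages
#' (pairwise-complete); zero-variance variants have r-squared 0 with
#' everything and cannot clump anything. The window is a hard bound: SNPs
#' beyond it are never clumped, whatever their r-squared.
#'
#' @param weights harmonized (ok-status) weights.
#' @param G the [genotype_matrix()] supplying LD.
#' @param spec a [clump_spec()].
#' @return the index-SNP rows of `weights`, in selection order.
#' @export
ld_clump <- function(weights, G, spec = clump_spec()) {
  w <- ok_weights(weights)
  if (!nrow(w)) return(w)
  w <- w[order(w$p, w$bp), , drop = FALSE]
  window_bp <- spec$window_kb * 1000
  alive <- rep(TRUE, nrow(w))
  picked <- integer()
  while (any(alive)) {
    i <- which(alive)[1]           # smallest p among survivors
    picked <- c(picked, i)
    alive[i] <- FALSE
    cand <- which(alive & w$chrom == w$chrom[i] &
                    abs(w$bp - w$bp[i]) <= window_bp)
    if (length(cand)) {
      r2 <- dosage_r2(G$dosage, w$variant_index[i], w$variant_index[cand])
      alive[cand[r2 > spec$r2_max]] <- FALSE
    }
  }
  w[picked, , drop = FALSE]
}

#' Compute polygenic scores
#'
#' Weighted sum of alt-allele dosages: score_i = sum_j beta_alt_j *
#' dosage_ij over the (clumped) weights. Missing dosages are by default
#' mean-imputed as 2 x the alt-allele frequency observed in `G` (the
#' PLINK --score convention); `missing_policy = "omit"` skips the term
#' instead.
#'
#' @param G a [genotype_matrix()].
#' @param weights clumped ok-status weights.
#' @param missing_policy "mean_impute" (default) or "omit".
#' @return named numeric vector of per-sample scores with attribute
#'   `n_snps_used`; all-NA with `n_snps_used = 0` for an empty weight list.
#' @export
compute_prs <- function(G, weights, missing_policy = c("mean_impute", "omit")) {
  missing_policy <- match.arg(missing_policy)
  w <- ok_weights(weights)
  if (!nrow(w)) {
    out <- stats::setNames(rep(NA_real_, length(G$sample_ids)), G$sample_ids)
    attr(out, "n_snps_used") <- 0L
    return(out)
  }
  d <- G$dosage[, w$variant_index, drop = FALSE]
  if (anyNA(d)) {
    if (missing_policy == "mean_impute") {
      af2 <- colMeans(d, na.rm = TRUE)   # 2 x alt-allele frequency
      for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- af2[j]
    } else d[is.na(d)] <- 0
  }
  out <- drop(d %*% w$beta_alt)
  names(out) <- G$sample_ids
  attr(out, "n_snps_used") <- nrow(w)
  out
}

#' Build the full score grid
#'
#' For each score label (genome-wide plus one per pathway), each P-value
#' threshold, and each APOE mode, applies: pathway restriction (pathway
#' scores only) -> APOE region mask -> P-threshold -> LD clump -> score.
#' An empty column (no surviving SNPs) is recorded as all-missing with
#' n_snps_used = 0 rather than aborting the grid.
#'
#' @param G a [genotype_matrix()].
#' @param weights harmonized weights (see [harmonize_weights()]).
#' @param pathway_sets list from [build_pathway_snp_sets()].
#' @param spec a [clump_spec()]; scores are built at every threshold in
#'   `spec$p_thresholds`.
#' @param apoe a [region_spec()].
#' @param apoe_modes subset of c("with_apoe", "no_apoe", "apoe_only").
#' @param clump_scope "pathway" (default; clump within the restricted SNP
#'   set) or "genomewide" (clump first, then restrict to the pathway).
#' @return A `score_table`: list with `scores` (data.frame sample_id +
#'   one column per grid cell) and `meta` (data.frame column, score_label,
#'   threshold, apoe_mode, n_snps_used).
#' @export
build_score_matrix <- function(G, weights, pathway_sets = list(),
                               spec = clump_spec(), apoe = region_spec(),
                               apoe_modes = c("with_apoe", "no_apoe",
                                              "apoe_only"),
                               clump_scope = c("pathway", "genomewide")) {
  clump_scope <- match.arg(clump_scope)
  labels <- c(list(NULL), pathway_sets)
  names(labels) <- c("genome_wide",
                     vapply(pathway_sets, `[[`, "", "pathway_id"))
  scores <- data.frame(sample_id = G$sample_ids, stringsAsFactors = FALSE)
  meta <- list()
  base <- ok_weights(weights)
  gw_clumped <- NULL
  if (clump_scope == "genomewide") gw_clumped <- list()
  for (lab in names(labels)) {
    for (mode in apoe_modes) {
      masked <- switch(mode,
                       with_apoe = base,
                       no_apoe = exclude_region(base, apoe, "exclude"),
                       apoe_only = exclude_region(base, apoe, "only"))
      for (pT in spec$p_thresholds) {
        sel <- suppressWarnings(threshold_by_p(masked, pT))
        if (clump_scope == "genomewide") {
          key <- paste(mode, pT)
          if (is.null(gw_clumped[[key]]))
            gw_clumped[[key]] <- ld_clump(sel, G, spec)
          cl <- gw_clumped[[key]]
          if (lab != "genome_wide")
            cl <- suppressWarnings(restrict_to_pathway(cl, labels[[lab]]))
        } else {
          if (lab != "genome_wide")
            sel <- suppressWarnings(restrict_to_pathway(sel, labels[[lab]]))
          cl <- ld_clump(sel, G, spec)
        }
        sc <- compute_prs(G, cl)
        col <- score_column_name(lab, pT, mode)
        scores[[col]] <- as.numeric(sc)
        meta[[col]] <- data.frame(column = col, score_label = lab,
                                  threshold = pT, apoe_mode = mode,
                                  n_snps_used = attr(sc, "n_snps_used"),
                                  stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(scores = scores, meta = do.call(rbind, c(meta, list(
    make.row.names = FALSE)))), class = "score_table")
}

score_column_name <- function(label, pT, mode) {
  paste(label, format(pT, scientific = TRUE, trim = TRUE), mode, sep = "|")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d samples x %d score columns\n",
              nrow(x$scores), nrow(x$meta)))
  invisible(x)
}

#' Write a score table as TSV
#'
#' @param st a `score_table`.
#' @param path output TSV (sample_id + one column per score cell).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(st, path) {
  utils::write.table(st$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
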