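#' Synthetic-cohort configuration
#'
#' Defines the generative law for a desk-scale cohort with the structure
#' the scoring pipeline assumes: LD-block diploid genotypes, an
#' independent discovery GWAS with planted per-pathway effects, gene sets
#' that tile the chromosome (and may overlap), an APOE-like large-effect
#' region, and ROI phenotypes linear in causal dosages plus covariates
#' plus Gaussian noise.
#'
#' Genotypes: haplotypes per LD block come from a latent
#' exchangeable-correlation Gaussian (correlation `within_block_r`)
#' thresholded at each variant's MAF quantile; dosage is the sum of two
#' independent haplotypes; blocks are independent. ROI construction:
#' `roi = mu + scale * (sign * effect_size * z_g + covariate term +
#' N(0, noise_sd))` where `z_g` is the standardized planted genetic
#' component of the ROI's linked pathway; `effect_size` is therefore the
#' standardized (per phenotype-SD-ish) coefficient. ROIs with no linked
#' pathway are null.
#'
#' @param seed base RNG seed; all stage seeds derive from it.
#' @param n_target,n_discovery target and discovery cohort sizes.
#' @param n_snps number of variants (one chromosome, evenly spaced).
#' @param block_size SNPs per LD block (must divide n_snps).
#' @param within_block_r latent within-block correlation in \[0, 1).
#' @param maf_range MAF bounds, drawn uniformly per variant.
#' @param missing_rate target-cohort missing-call rate.
#' @param n_genes genes tiling the chromosome (must divide n_snps).
#' @param chrom,bp_start,bp_step variant coordinate layout.
#' @param pathways list of lists: pathway_id, description, genes (gene
#'   indices), effect_mean, effect_sd (per-dosage liability effects of the
#'   pathway's SNPs; mean 0 = null pathway).
#' @param apoe_like_region a [region_spec()] inside the simulated
#'   coordinates, or NULL for none.
#' @param apoe_effect liability effect of one planted SNP at the start of
#'   the APOE-like region (0 disables).
#' @param discovery_noise_sd liability noise SD in the discovery GWAS.
#' @param rois data.frame (name, family, mu, scale, pathway_id, sign,
#'   effect_size) describing ROI phenotypes; pathway_id NA = null ROI.
#' @param covariate_effects named numeric: per-SD effects of age, sex,
#'   icv on every ROI (in ROI-scale units).
#' @param noise_sd ROI noise SD (in ROI-scale units).
#' @param n_pcs ancestry PCs computed from the target genotypes and
#'   included as covariates.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_target = 2000L, n_discovery = 4000L,
                       n_snps = 500L, block_size = 10L,
                       within_block_r = 0.8,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.01,
                       n_genes = 50L,
                       chrom = "19", bp_start = 40000001L, bp_step = 10000L,
                       pathways = NULL,
                       apoe_like_region = region_spec("19", 44400000L,
                                                      46500000L),
                       apoe_effect = 0.3,
                       discovery_noise_sd = 1,
                       rois = NULL,
                       covariate_effects = c(age = -0.1, sex = 0.05,
                                             icv = 0.2),
                       noise_sd = 1,
                       n_pcs = 5L) {
  if (n_snps %% block_size != 0) stop("block_size must divide n_snps")
  if (n_snps %% n_genes != 0) stop("n_genes must divide n_snps")
  if (within_block_r < 0 || within_block_r >= 1)
    stop("within_block_r must lie in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(pathways)) pathways <- default_sim_pathways()
  if (is.null(rois)) rois <- default_sim_rois()
  for (p in pathways)
    if (any(p$genes < 1 | p$genes > n_genes))
      stop("pathway ", p$pathway_id, " references nonexistent gene index")
  known <- c(NA, vapply(pathways, `[[`, "", "pathway_id"))
  if (!all(rois$pathway_id %in% known))
    stop("ROI linked to unknown pathway")
  structure(list(seed = as.integer(seed), n_target = as.integer(n_target),
                 n_discovery = as.integer(n_discovery),
                 n_snps = as.integer(n_snps),
                 block_size = as.integer(block_size),
                 within_block_r = within_block_r, maf_range = maf_range,
                 missing_rate = missing_rate, n_genes = as.integer(n_genes),
                 chrom = chrom, bp_start = as.integer(bp_start),
                 bp_step = as.integer(bp_step), pathways = pathways,
                 apoe_like_region = apoe_like_region,
                 apoe_effect = apoe_effect,
                 discovery_noise_sd = discovery_noise_sd, rois = rois,
                 covariate_effects = covariate_effects, noise_sd = noise_sd,
                 n_pcs = as.integer(n_pcs)),
            class = "sim_config")
}

# Three pathways emulating the published gene-set table's structure: two
# lipid/tau-like sets sharing genes and containing the APOE-like region,
# and one large immune-like set that excludes it.
default_sim_pathways <- function() {
  list(list(pathway_id = "pw_tau", description = "tau-binding analogue",
            genes = c(1:4, 45L), effect_mean = 0.08, effect_sd = 0.02),
       list(pathway_id = "pw_chol",
            description = "reverse-cholesterol analogue",
            genes = c(4:8, 46L), effect_mean = 0.08, effect_sd = 0.02),
       list(pathway_id = "pw_immune", description = "immune analogue",
            genes = 20:30, effect_mean = 0.08, effect_sd = 0.02))
}

default_sim_rois <- function() {
  data.frame(
    name = c("left_middle_temporal", "right_posterior_cingulate",
             "left_superior_parietal", "right_inferior_parietal",
             "left_hippocampus", "right_hippocampus", "left_thalamus",
             "left_amygdala"),
    family = rep(c("cortical", "subcortical"), each = 4),
    mu = c(rep(2.5, 4), rep(4000, 4)),
    scale = c(rep(0.15, 4), rep(400, 4)),
    pathway_id = c("pw_chol", "pw_immune", NA, NA, "pw_tau", NA, NA, NA),
    sign = c(-1, -1, NA, NA, -1, NA, NA, NA),
    effect_size = c(0.15, 0.15, NA, NA, 0.15, NA, NA, NA),
    stringsAsFactors = FALSE)
}

# Deterministic variant law: coordinates, block membership and per-variant
# MAFs, all fixed by cfg$seed.
sim_variant_law <- function(cfg) {
  set.seed(cfg$seed)
  bp <- cfg$bp_start + (seq_len(cfg$n_snps) - 1L) * cfg$bp_step
  data.frame(variant_id = sprintf("snp%04d", seq_len(cfg$n_snps)),
             chrom = cfg$chrom, bp = bp, ref = "A", alt = "G",
             block = rep(seq_len(cfg$n_snps %/% cfg$block_size),
                         each = cfg$block_size),
             maf = stats::runif(cfg$n_snps, cfg$maf_range[1],
                                cfg$maf_range[2]),
             gene = rep(seq_len(cfg$n_genes),
                        each = cfg$n_snps %/% cfg$n_genes),
             stringsAsFactors = FALSE)
}

sim_gene_table <- function(cfg, law = sim_variant_law(cfg)) {
  agg_start <- tapply(law$bp, law$gene, min)
  agg_end <- tapply(law$bp, law$gene, max)
  data.frame(gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
             chrom = cfg$chrom, start_bp = as.integer(agg_start),
             end_bp = as.integer(agg_end), stringsAsFactors = FALSE)
}

# One haplotype matrix (n x m) for one block: exchangeable latent Gaussian
# thresholded at each variant's MAF quantile (minor allele = 1... the alt
# allele frequency equals the MAF draw).
draw_block_haplotype <- function(n, maf, r) {
  m <- length(maf)
  shared <- stats::rnorm(n)
  z <- sqrt(r) * shared +
    sqrt(1 - r) * matrix(stats::rnorm(n * m), n, m)
  sweep(z, 2, stats::qnorm(maf), `<`) + 0
}

#' Simulate LD-structured diploid genotypes
#'
#' Draws the cohort named by `role` from the variant law fixed by the
#' config seed. Dosage = sum of two independent haplotypes; blocks are
#' independent; missing calls (target cohort only) are planted uniformly
#' at `missing_rate`. Variants that come out monomorphic are redrawn
#' (bounded retries). Fully reproducible from the seed.
#'
#' @param cfg a [sim_config()].
#' @param role "target" or "discovery" (independent cohorts, same law).
#' @return a [genotype_matrix()] with attribute `maf` (the law's MAFs).
#' @export
simulate_genotypes <- function(cfg, role = c("target", "discovery")) {
  role <- match.arg(role)
  law <- sim_variant_law(cfg)
  n <- if (role == "target") cfg$n_target else cfg$n_discovery
  set.seed(cfg$seed + if (role == "target") 1L else 2L)
  d <- matrix(0, n, cfg$n_snps)
  for (b in unique(law$block)) {
    j <- which(law$block == b)
    d[, j] <- draw_block_haplotype(n, law$maf[j], cfg$within_block_r) +
      draw_block_haplotype(n, law$maf[j], cfg$within_block_r)
  }
  for (j in seq_len(cfg$n_snps)) {
    tries <- 0
    while (length(unique(d[, j])) == 1) {
      tries <- tries + 1
      if (tries > 50) stop("variant ", j, " monomorphic after 50 redraws")
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      d[, j] <- (z1 < stats::qnorm(law$maf[j])) + (z2 < stats::qnorm(law$maf[j]))
    }
  }
  if (role == "target" && cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * cfg$n_snps) < cfg$missing_rate,
                   n, cfg$n_snps)
    d[miss] <- NA
  }
  prefix <- if (role == "target") "T" else "D"
  G <- genotype_matrix(d, sprintf("%s%05d", prefix, seq_len(n)),
                       law[, c("variant_id", "chrom", "bp", "ref", "alt")])
  attr(G, "maf") <- law$maf
  G
}

# Planted per-SNP liability effects, fixed by the seed: each SNP of each
# pathway's genes gets effect ~ N(effect_mean, effect_sd); overlapping
# pathways add; one large-effect SNP at the start of the APOE-like region.
planted_effects <- function(cfg, law = sim_variant_law(cfg)) {
  set.seed(cfg$seed + 3L)
  per_pathway <- list()
  total <- numeric(cfg$n_snps)
  for (p in cfg$pathways) {
    e <- numeric(cfg$n_snps)
    j <- which(law$gene %in% p$genes)
    e[j] <- stats::rnorm(length(j), p$effect_mean, p$effect_sd)
    per_pathway[[p$pathway_id]] <- e
    total <- total + e
  }
  apoe_idx <- NA_integer_
  if (!is.null(cfg$apoe_like_region) && cfg$apoe_effect != 0) {
    inside <- which(law$chrom == cfg$apoe_like_region$chrom &
                      law$bp >= cfg$apoe_like_region$start_bp &
                      law$bp <= cfg$apoe_like_region$end_bp)
    if (length(inside)) {
      apoe_idx <- inside[1]
      total[apoe_idx] <- total[apoe_idx] + cfg$apoe_effect
    }
  }
  list(per_pathway = per_pathway, total = total, apoe_index = apoe_idx)
}

#' Simulate gene and pathway annotation files' content
#'
#' Genes tile the simulated chromosome (each gene covers a run of
#' consecutive SNPs); pathways are the configured gene-index sets, which
#' may share genes.
#'
#' @param cfg a [sim_config()].
#' @return list with `genes` (data.frame) and `pathways` (list), in the
#'   shapes returned by [read_gene_sets()].
#' @export
simulate_annotation <- function(cfg) {
  genes <- sim_gene_table(cfg)
  pathways <- lapply(cfg$pathways, function(p)
    list(pathway_id = p$pathway_id, description = p$description,
         gene_ids = genes$gene_id[p$genes]))
  list(genes = genes, pathways = pathways)
}

#' Simulate a discovery GWAS and its summary statistics
#'
#' Draws an independent discovery cohort from the same genotype law,
#' forms a quantitative liability (sum of planted effects times dosage
#' plus Gaussian noise) and runs a per-SNP marginal OLS, yielding betas
#' and P-values in the canonical summary-statistic schema. (A log-OR
#' reading of the betas only changes the scores' scale.)
#'
#' @param cfg a [sim_config()].
#' @return summary-statistics data.frame (as [read_summary_stats()]
#'   returns) with attribute `truth` (the planted effect structure).
#' @export
simulate_discovery_sumstats <- function(cfg) {
  law <- sim_variant_law(cfg)
  G <- simulate_genotypes(cfg, "discovery")
  eff <- planted_effects(cfg, law)
  n <- cfg$n_discovery
  set.seed(cfg$seed + 4L)
  y <- drop(G$dosage %*% eff$total) +
    stats::rnorm(n, 0, cfg$discovery_noise_sd)
  X <- scale(G$dosage, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(X^2)
  sxy <- drop(crossprod(X, yc))
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta * sxy
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), n - 2)
  p[p == 0] <- .Machine$double.xmin  # keep inside (0, 1]
  out <- data.frame(variant_id = law$variant_id, chrom = law$chrom,
                    bp = law$bp, a1 = law$alt, a2 = law$ref,
                    beta = beta, p = p, maf = attr(G, "maf"),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- eff
  out
}

#' Simulate target ROI phenotypes and covariates
#'
#' Covariates: age (years), sex (0/1), ICV (mm^3), site and array (0/1
#' codes) and the leading ancestry PCs computed from the target genotypes
#' themselves via [compute_pcs()] (mirroring the real pipeline's
#' circularity). Each ROI linked to a pathway receives
#' `sign * effect_size` standard units of that pathway's planted genetic
#' component; unlinked ROIs are covariates + noise only.
#'
#' @param G the target [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @return phenotype data.frame with attributes `roi_cols`,
#'   `covariate_cols` and `truth` (ROI-to-pathway links).
#' @export
simulate_target_phenotypes <- function(G, cfg) {
  law <- sim_variant_law(cfg)
  if (!identical(law$variant_id, G$variants$variant_id))
    stop("genotypes do not match the config's variant law")
  eff <- planted_effects(cfg, law)
  n <- length(G$sample_ids)
  pcs <- compute_pcs(G, cfg$n_pcs)
  set.seed(cfg$seed + 5L)
  cov_tab <- data.frame(
    sample_id = G$sample_ids,
    age = round(stats::rnorm(n, 55, 8), 1),
    sex = stats::rbinom(n, 1, 0.5),
    icv = round(stats::rnorm(n, 1.5e6, 1.3e5)),
    site = stats::rbinom(n, 1, 0.5),
    array = stats::rbinom(n, 1, 0.1),
    stringsAsFactors = FALSE)
  cov_tab <- cbind(cov_tab, as.data.frame(pcs))
  d <- G$dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  }
  cov_term <- numeric(n)
  for (nm in names(cfg$covariate_effects)) {
    v <- cov_tab[[nm]]
    if (is.null(v)) stop("covariate_effects names unknown covariate: ", nm)
    cov_term <- cov_term + cfg$covariate_effects[[nm]] * as.numeric(scale(v))
  }
  ph <- cov_tab
  for (i in seq_len(nrow(cfg$rois))) {
    r <- cfg$rois[i, ]
    g_term <- 0
    if (!is.na(r$pathway_id)) {
      e <- eff$per_pathway[[r$pathway_id]]
      if (all(e == 0)) stop("ROI ", r$name, " linked to effect-free pathway")
      g <- drop(d %*% e)
      g_term <- r$sign * r$effect_size * as.numeric(scale(g))
    }
    ph[[r$name]] <- r$mu + r$scale *
      (g_term + cov_term + stats::rnorm(n, 0, cfg$noise_sd))
  }
  roi_cols <- cfg$rois$name
  cov_cols <- c("age", "sex", "icv", "site", "array", colnames(pcs))
  ph <- ph[, c("sample_id", roi_cols, cov_cols)]
  attr(ph, "roi_cols") <- roi_cols
  attr(ph, "covariate_cols") <- cov_cols
  attr(ph, "truth") <- cfg$rois
  ph
}

#' Write a complete synthetic cohort to disk
#'
#' Emits genotypes.vcf, sumstats.tsv, genes.bed, pathways.gmt,
#' phenotypes.tsv and truth.json (the planted effects, for recovery
#' tests). Byte-identical across runs with the same config.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the six file paths, invisibly.
#' @export
simulate_cohort <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  law <- sim_variant_law(cfg)
  ann <- simulate_annotation(cfg)
  G <- simulate_genotypes(cfg, "target")
  stats <- simulate_discovery_sumstats(cfg)
  ph <- simulate_target_phenotypes(G, cfg)
  eff <- attr(stats, "truth")
  paths <- c(genotypes = file.path(out_dir, "genotypes.vcf"),
             sumstats = file.path(out_dir, "sumstats.tsv"),
             genes = file.path(out_dir, "genes.bed"),
             pathways = file.path(out_dir, "pathways.gmt"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_genotypes(G, paths["genotypes"], "vcf")
  write_summary_stats(stats, paths["sumstats"])
  write_gene_sets(ann$genes, ann$pathways, paths["genes"], paths["pathways"])
  write_phenotype_table(ph, paths["phenotypes"])
  jsonlite::write_json(
    list(seed = cfg$seed,
         planted_total = eff$total,
         per_pathway = eff$per_pathway,
         apoe_index = eff$apoe_index,
         rois = cfg$rois),
    paths["truth"], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
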