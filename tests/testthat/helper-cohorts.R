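# Cohort-level experiment harnesses used by the acceptance suite: each
# builds a full synthetic cohort with the package generator, scores it and
# runs the association grid, without file round-trips (those are exercised
# by the pipeline tests).

score_and_associate <- function(cfg, p_thresholds, apoe_modes = "with_apoe",
                                clump = NULL) {
  G <- simulate_genotypes(cfg, "target")
  stats <- simulate_discovery_sumstats(cfg)
  ann <- simulate_annotation(cfg)
  ph <- simulate_target_phenotypes(G, cfg)
  m <- map_snps_to_genes(G$variants, ann$genes, 0)
  ps <- suppressWarnings(
    build_pathway_snp_sets(ann$pathways, m, G$variants, stats$variant_id,
                           cfg$apoe_like_region))
  w <- harmonize_weights(stats, G)
  if (is.null(clump))
    clump <- clump_spec(p_thresholds = p_thresholds,
                        primary_threshold = max(p_thresholds))
  st <- suppressWarnings(
    build_score_matrix(G, w, ps, clump, cfg$apoe_like_region,
                       apoe_modes = apoe_modes))
  res <- run_association_grid(st, ph, split(cfg$rois$name, cfg$rois$family),
                              attr(ph, "covariate_cols"))
  list(G = G, ph = ph, scores = st, res = res, pathway_sets = ps,
       weights = w, stats = stats)
}

# Null study conditions: 1000 target samples, 500 SNPs in blocks of 10,
# three (effect-free) pathways, ten null ROIs — no planted effects at all.
null_cohort_cfg <- function(seed) {
  paths <- default_sim_pathways()
  for (i in seq_along(paths)) {
    paths[[i]]$effect_mean <- 0
    paths[[i]]$effect_sd <- 0
  }
  rois <- data.frame(
    name = c(sprintf("thick%d", 1:5), sprintf("vol%d", 1:5)),
    family = rep(c("cortical", "subcortical"), each = 5),
    mu = rep(c(2.5, 4000), each = 5), scale = rep(c(0.15, 400), each = 5),
    pathway_id = NA_character_, sign = NA_real_, effect_size = NA_real_,
    stringsAsFactors = FALSE)
  sim_config(seed = seed, n_target = 1000, n_discovery = 1000,
             pathways = paths, apoe_effect = 0, rois = rois, n_pcs = 3L)
}

# Planted-effect study conditions: standardized pathway effects of 0.15 on
# three ROIs (defaults), target n = 2000.
power_cohort_cfg <- function(seed) sim_config(seed = seed, n_pcs = 3L)

# Older/younger direction-flip conditions: the same pathway drives
# hippocampal volume down in one ROI set and up in the other.
flip_cohort_cfg <- function(seed) {
  rois <- data.frame(
    name = c("hippocampus_old", "hippocampus_young", "vol_null"),
    family = "subcortical", mu = 4000, scale = 400,
    pathway_id = c("pw_tau", "pw_tau", NA),
    sign = c(-1, 1, NA), effect_size = c(0.15, 0.15, NA),
    stringsAsFactors = FALSE)
  sim_config(seed = seed, rois = rois, n_pcs = 3L)
}

# Dense-weak-effect conditions: every SNP carries a small N(0, 0.05)
# liability effect through one chromosome-wide pathway; one ROI loads on
# the whole component, so lenient thresholds add true signal.
trend_cohort_cfg <- function(seed) {
  sim_config(seed = seed, n_target = 2000, n_discovery = 6000,
             pathways = list(list(pathway_id = "pw_dense",
                                  description = "dense weak effects",
                                  genes = 1:50, effect_mean = 0,
                                  effect_sd = 0.05)),
             rois = data.frame(name = "roi_dense", family = "cortical",
                               mu = 2.5, scale = 0.15,
                               pathway_id = "pw_dense", sign = -1,
                               effect_size = 0.3),
             n_pcs = 2L)
}
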