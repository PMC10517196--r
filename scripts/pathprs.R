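#!/usr/bin/env Rscript

# Thin command-line front end over the pathprs package.
#
#   Rscript scripts/pathprs.R simulate --out DIR [--seed N] [--n-target N]
#       [--n-discovery N] [--n-snps N]
#   Rscript scripts/pathprs.R pipeline --config cfg.yaml
#
# The pipeline YAML config maps 1:1 onto pipeline_config(); see README.

suppressMessages({
  library(optparse)
  library(pathprs)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("simulate", "pipeline")) {
  stop("usage: pathprs.R {simulate|pipeline} [options]", call. = FALSE)
}
cmd <- args[1]
rest <- args[-1]

if (cmd == "simulate") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--out", type = "character"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--n-target", type = "integer", default = 2000L,
                dest = "n_target"),
    make_option("--n-discovery", type = "integer", default = 4000L,
                dest = "n_discovery"),
    make_option("--n-snps", type = "integer", default = 500L,
                dest = "n_snps"))), args = rest)
  if (is.null(o$out)) stop("--out is required")
  cfg <- sim_config(seed = o$seed, n_target = o$n_target,
                    n_discovery = o$n_discovery, n_snps = o$n_snps)
  paths <- simulate_cohort(cfg, o$out)
  cat("wrote:\n"); for (p in paths) cat(" ", p, "\n")
} else {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character"))), args = rest)
  if (is.null(o$config)) stop("--config is required")
  y <- yaml::read_yaml(o$config)
  qc_args <- y$qc %||% list()
  clump_args <- y$clump %||% list()
  apoe <- if (!is.null(y$apoe_region))
    do.call(region_spec, y$apoe_region) else region_spec()
  cfg <- pipeline_config(
    out_dir = y$out_dir,
    genotypes_path = y$inputs$genotypes,
    sumstats_path = y$inputs$sumstats,
    genes_bed_path = y$inputs$genes_bed,
    pathways_gmt_path = y$inputs$pathways_gmt,
    phenotypes_path = y$inputs$phenotypes,
    genotype_format = y$inputs$genotype_format %||% "vcf",
    roi_families = lapply(y$roi_families, unlist),
    covariate_cols = unlist(y$covariate_cols),
    qc = do.call(qc_thresholds, qc_args),
    clump = do.call(clump_spec, clump_args),
    apoe_region = apoe,
    gene_window_kb = y$gene_window_kb %||% 0,
    clump_scope = y$clump_scope %||% "pathway",
    n_pcs = y$n_pcs %||% 5L,
    fdr_scope = y$fdr_scope %||% "family",
    standardize_scores = y$standardize_scores %||% TRUE)
  run_pipeline(cfg)
}
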