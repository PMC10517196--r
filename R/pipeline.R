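#' Pipeline configuration
#'
#' Binds every stage parameter of the end-to-end analysis: input paths
#' (or a simulation config standing in for them), QC thresholds, clumping
#' spec, APOE region, grid options, output directory and seed.
#'
#' @param out_dir output directory.
#' @param sim a [sim_config()] to generate the inputs, or NULL to read
#'   the paths below.
#' @param genotypes_path,sumstats_path,genes_bed_path,pathways_gmt_path,
#'   phenotypes_path input files (ignored when `sim` is given).
#' @param genotype_format "vcf" or "dosage".
#' @param roi_families named list family -> ROI columns; defaults to the
#'   simulation's families when `sim` is given.
#' @param covariate_cols covariate columns of the phenotype table
#'   (ancestry PCs recomputed from the genotypes are appended).
#' @param qc a [qc_thresholds()].
#' @param clump a [clump_spec()].
#' @param apoe_region a [region_spec()].
#' @param apoe_modes score-grid APOE modes (apoe_only is always added:
#'   it is the variance-attribution comparator).
#' @param gene_window_kb SNP-to-gene flanking window.
#' @param clump_scope "pathway" or "genomewide" (see
#'   [build_score_matrix()]).
#' @param n_pcs ancestry PCs to compute and adjust for.
#' @param fdr_scope "family" or "joint".
#' @param standardize_scores z-standardize scores before regression.
#' @param seed seed echoed into the run report (the analysis stages are
#'   deterministic; only simulation consumes it, via `sim$seed`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            sim = NULL,
                            genotypes_path = NULL, sumstats_path = NULL,
                            genes_bed_path = NULL, pathways_gmt_path = NULL,
                            phenotypes_path = NULL,
                            genotype_format = "vcf",
                            roi_families = NULL,
                            covariate_cols = c("age", "sex", "icv", "site",
                                               "array"),
                            qc = qc_thresholds(),
                            clump = clump_spec(),
                            apoe_region = region_spec(),
                            apoe_modes = c("with_apoe", "no_apoe"),
                            gene_window_kb = 0,
                            clump_scope = "pathway",
                            n_pcs = 5L,
                            fdr_scope = "family",
                            standardize_scores = TRUE,
                            seed = if (!is.null(sim)) sim$seed else 1L) {
  if (is.null(sim)) {
    paths <- c(genotypes_path, sumstats_path, genes_bed_path,
               pathways_gmt_path, phenotypes_path)
    if (length(paths) < 5) stop("either sim or all five input paths required")
    missing_f <- paths[!file.exists(paths)]
    if (length(missing_f))
      stop("input file(s) not found: ", paste(missing_f, collapse = ", "))
    if (is.null(roi_families)) stop("roi_families required for file inputs")
  } else if (is.null(roi_families)) {
    roi_families <- split(sim$rois$name, sim$rois$family)
  }
  structure(list(out_dir = out_dir, sim = sim,
                 genotypes_path = genotypes_path,
                 sumstats_path = sumstats_path,
                 genes_bed_path = genes_bed_path,
                 pathways_gmt_path = pathways_gmt_path,
                 phenotypes_path = phenotypes_path,
                 genotype_format = genotype_format,
                 roi_families = roi_families,
                 covariate_cols = covariate_cols,
                 qc = qc, clump = clump, apoe_region = apoe_region,
                 apoe_modes = apoe_modes, gene_window_kb = gene_window_kb,
                 clump_scope = clump_scope, n_pcs = as.integer(n_pcs),
                 fdr_scope = fdr_scope,
                 standardize_scores = standardize_scores,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_stage <- function(name, report, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline aborted at stage '%s': %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline
#'
#' Stages, each persisting its output under `cfg$out_dir`:
#' simulate/ingest -> sample QC -> variant QC -> ROI outlier removal ->
#' ancestry PCs -> pathway annotation -> weight harmonization -> score
#' grid -> association grid. A rerun with the same config and seed
#' reproduces every output byte-identically.
#'
#' @param cfg a [pipeline_config()].
#' @return the run report (list), invisibly; written as run_report.json.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed,
                 parameters = list(
                   maf_min = cfg$qc$maf_min,
                   variant_call_min = cfg$qc$variant_call_min,
                   sample_call_min = cfg$qc$sample_call_min,
                   hwe_p_min = cfg$qc$hwe_p_min,
                   roi_outlier_sd = cfg$qc$roi_outlier_sd,
                   clump_r2 = cfg$clump$r2_max,
                   clump_kb = cfg$clump$window_kb,
                   p_thresholds = cfg$clump$p_thresholds,
                   primary_threshold = cfg$clump$primary_threshold,
                   apoe_region = sprintf("%s:%d-%d", cfg$apoe_region$chrom,
                                         cfg$apoe_region$start_bp,
                                         cfg$apoe_region$end_bp),
                   gene_window_kb = cfg$gene_window_kb,
                   clump_scope = cfg$clump_scope, n_pcs = cfg$n_pcs,
                   fdr_scope = cfg$fdr_scope,
                   standardize_scores = cfg$standardize_scores),
                 stages = list())
  log_stage <- function(name, ...) {
    msg <- sprintf(...)
    message(sprintf("[%s] %s", name, msg))
    report$stages[[name]] <<- msg
  }

  pipeline_stage("input", report, {
    if (!is.null(cfg$sim)) {
      paths <- simulate_cohort(cfg$sim, file.path(cfg$out_dir, "sim"))
      cfg$genotypes_path <- paths[["genotypes"]]
      cfg$sumstats_path <- paths[["sumstats"]]
      cfg$genes_bed_path <- paths[["genes"]]
      cfg$pathways_gmt_path <- paths[["pathways"]]
      cfg$phenotypes_path <- paths[["phenotypes"]]
      cfg$genotype_format <- "vcf"
    }
    G <- read_genotypes(cfg$genotypes_path, cfg$genotype_format)
    stats <- read_summary_stats(cfg$sumstats_path)
    gs <- read_gene_sets(cfg$pathways_gmt_path, cfg$genes_bed_path)
    ph <- read_phenotype_table(cfg$phenotypes_path,
                                roi_cols = unlist(cfg$roi_families,
                                                  use.names = FALSE),
                                covariate_cols = cfg$covariate_cols)
    log_stage("input", "%d samples, %d variants, %d sumstat rows, %d pathways",
              length(G$sample_ids), nrow(G$variants), nrow(stats),
              length(gs$pathways))
  })

  pipeline_stage("qc_samples", report, {
    fs <- filter_samples(G, cfg$qc)
    G <- fs$genotypes
    utils::write.table(fs$report, file.path(cfg$out_dir, "qc_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("qc_samples", "%d of %d samples retained",
              length(G$sample_ids), nrow(fs$report))
  })

  pipeline_stage("qc_variants", report, {
    fv <- filter_variants(G, cfg$qc)
    if (length(fv$genotypes$sample_ids) == 0 ||
        nrow(fv$genotypes$variants) == 0)
      stop("no variants survive QC")
    G <- fv$genotypes
    utils::write.table(fv$report, file.path(cfg$out_dir, "qc_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cnt <- attr(fv$report, "counts")
    log_stage("qc_variants",
              "%d variants removed (call_rate %d, maf %d, hwe %d); %d retained",
              cnt[["removed"]], cnt[["call_rate"]], cnt[["maf"]],
              cnt[["hwe"]], nrow(G$variants))
  })

  pipeline_stage("qc_phenotypes", report, {
    ph <- ph[ph$sample_id %in% G$sample_ids, , drop = FALSE]
    ro <- remove_roi_outliers(ph, cfg$qc)
    ph <- ro$phenotypes
    utils::write.table(ro$report, file.path(cfg$out_dir, "qc_rois.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("qc_phenotypes", "%d ROI value(s) set missing",
              sum(ro$report$n_removed))
  })

  pipeline_stage("pcs", report, {
    pcs <- compute_pcs(G, cfg$n_pcs)
    pc_cols <- colnames(pcs)
    ph <- cbind(ph[setdiff(names(ph), pc_cols)],
                 as.data.frame(pcs)[match(ph$sample_id, rownames(pcs)), ,
                                    drop = FALSE])
    covariates <- c(cfg$covariate_cols, pc_cols)
    log_stage("pcs", "%d ancestry PCs recomputed post-QC", ncol(pcs))
  })

  pipeline_stage("annotate", report, {
    snp_gene <- map_snps_to_genes(G$variants, gs$genes, cfg$gene_window_kb)
    psets <- build_pathway_snp_sets(gs$pathways, snp_gene, G$variants,
                                     stats$variant_id, cfg$apoe_region)
    write_pathway_counts(psets, file.path(cfg$out_dir,
                                          "pathway_snp_counts.tsv"))
    log_stage("annotate", "pathway SNP sets: %s",
              paste(sprintf("%s=%d", attr(psets, "counts")$pathway_id,
                            attr(psets, "counts")$n_snps), collapse = ", "))
  })

  pipeline_stage("score", report, {
    w <- harmonize_weights(stats, G)
    cnt <- attr(w, "counts")
    st <- build_score_matrix(G, w, psets, cfg$clump, cfg$apoe_region,
                              apoe_modes = unique(c(cfg$apoe_modes,
                                                    "apoe_only")),
                              clump_scope = cfg$clump_scope)
    write_score_table(st, file.path(cfg$out_dir, "scores.tsv"))
    utils::write.table(st$meta, file.path(cfg$out_dir, "score_meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("score", "%d ok weights (%d ambiguous, %d mismatch); %d columns",
              cnt[["ok"]], cnt[["ambiguous_dropped"]],
              cnt[["mismatch_dropped"]], nrow(st$meta))
  })

  pipeline_stage("associate", report, {
    res <- run_association_grid(st, ph, cfg$roi_families, covariates,
                                 fdr_scope = cfg$fdr_scope,
                                 standardize = cfg$standardize_scores)
    write_association_table(res, file.path(cfg$out_dir, "associations.tsv"))
    log_stage("associate", "%d grid cells (%d unestimable)",
              nrow(res), sum(res$unestimable))
  })

  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, genotypes = G, scores = st,
                 associations = res, pathway_sets = psets))
}
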