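#' Map variants to genes by position
#'
#' A variant maps to a gene when its position lies within the gene body
#' extended by `window_kb` kilobases on each side, on the same chromosome.
#' A variant may map to several (overlapping) genes. Implemented with
#' \pkg{GenomicRanges} interval overlap.
#'
#' @param variants data.frame with variant_id, chrom, bp.
#' @param genes data.frame with gene_id, chrom, start_bp, end_bp.
#' @param window_kb flanking window in kb (default 0: gene body only).
#' @return named list: variant_id -> character vector of gene_ids
#'   (variants mapping to no gene are absent).
#' @export
map_snps_to_genes <- function(variants, genes, window_kb = 0) {
  if (window_kb < 0) stop("window_kb must be >= 0")
  w <- as.integer(round(window_kb * 1000))
  gr_v <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$bp, variants$bp))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(1L, genes$start_bp - w),
                                                  genes$end_bp + w))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_v, gr_g))
  qh <- S4Vectors::queryHits(hits)
  if (!length(qh)) return(structure(list(), names = character()))
  split(genes$gene_id[S4Vectors::subjectHits(hits)],
        factor(variants$variant_id[qh],
               levels = unique(variants$variant_id[qh])))
}

#' Resolve pathway gene sets to SNP sets matched to the discovery GWAS
#'
#' Each pathway's SNP set is the union, over its genes, of the variants
#' mapped to that gene, intersected with the variant IDs present in the
#' discovery summary statistics (sets are "matched to the discovery
#' sample"). Pathways may overlap in SNPs because they share genes. A
#' pathway is flagged as including the APOE region when any of its SNPs
#' lies inside `apoe_region`.
#'
#' @param pathways list of lists (pathway_id, description, gene_ids), as
#'   from [read_gene_sets()].
#' @param snp_gene_map mapping from [map_snps_to_genes()].
#' @param variants data.frame with variant_id, chrom, bp (target variants).
#' @param sumstat_ids character vector of variant IDs in the summary stats.
#' @param apoe_region a [region_spec()].
#' @return list of `pathway_snp_set` lists (pathway_id, description,
#'   gene_ids, snp_ids, n_genes_resolved, includes_apoe_region) with a
#'   `counts` attribute: the per-pathway count table (pathway_id,
#'   description, n_genes, n_genes_resolved, n_snps, includes_apoe).
#' @export
build_pathway_snp_sets <- function(pathways, snp_gene_map, variants,
                                   sumstat_ids,
                                   apoe_region = region_spec()) {
  map_ids <- names(snp_gene_map)
  usable <- intersect(map_ids, sumstat_ids)
  gene_of <- snp_gene_map[usable]
  # invert: gene -> SNPs (restricted to SNPs present in the summary stats)
  inv <- split(rep(usable, lengths(gene_of)), unlist(gene_of, use.names = FALSE))
  in_apoe <- variants$variant_id[variants$chrom == apoe_region$chrom &
                                   variants$bp >= apoe_region$start_bp &
                                   variants$bp <= apoe_region$end_bp]
  sets <- lapply(pathways, function(p) {
    hit_genes <- intersect(p$gene_ids, names(inv))
    snps <- unique(unlist(inv[hit_genes], use.names = FALSE))
    if (is.null(snps)) snps <- character()
    if (!length(snps))
      warning("pathway ", p$pathway_id, " resolves to 0 SNPs")
    structure(list(pathway_id = p$pathway_id, description = p$description,
                   gene_ids = p$gene_ids, snp_ids = snps,
                   n_genes_resolved = length(hit_genes),
                   includes_apoe_region = any(snps %in% in_apoe)),
              class = "pathway_snp_set")
  })
  counts <- data.frame(
    pathway_id = vapply(sets, `[[`, "", "pathway_id"),
    description = vapply(sets, `[[`, "", "description"),
    n_genes = vapply(sets, function(s) length(s$gene_ids), integer(1)),
    n_genes_resolved = vapply(sets, `[[`, integer(1), "n_genes_resolved"),
    n_snps = vapply(sets, function(s) length(s$snp_ids), integer(1)),
    includes_apoe = vapply(sets, `[[`, logical(1), "includes_apoe_region"),
    stringsAsFactors = FALSE)
  attr(sets, "counts") <- counts
  sets
}

#' Write the per-pathway SNP count table
#'
#' @param sets output of [build_pathway_snp_sets()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_pathway_counts <- function(sets, path) {
  utils::write.table(attr(sets, "counts"), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
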