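#' Read gene coordinates (BED) and pathway gene sets (GMT)
#'
#' The BED file supplies gene bodies (0-based half-open starts converted to
#' 1-based closed intervals on read); the GMT file supplies named gene
#' sets, one per line: set-ID, description, then member genes,
#' tab-delimited. Gene sets may overlap (share genes). Genes named in the
#' GMT but absent from the BED are reported as unresolvable; the pathway
#' keeps its remaining genes.
#'
#' @param gmt_path path to the GMT gene-set file.
#' @param bed_path path to the gene BED file (chrom, start, end, gene_id).
#' @return A list with `genes` (data.frame gene_id, chrom, start_bp,
#'   end_bp), `pathways` (list of lists with pathway_id, description,
#'   gene_ids), and `unresolved` (data.frame pathway_id, gene_id).
#' @export
read_gene_sets <- function(gmt_path, bed_path) {
  for (p in c(gmt_path, bed_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bed <- utils::read.table(bed_path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end", "gene_id"),
                           colClasses = c("character", "integer", "integer",
                                          "character"))
  genes <- data.frame(gene_id = bed$gene_id, chrom = bed$chrom,
                      start_bp = bed$start + 1L,  # BED is 0-based half-open
                      end_bp = bed$end, stringsAsFactors = FALSE)
  if (any(genes$start_bp > genes$end_bp)) stop("gene with start > end in BED")

  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) stop("malformed GMT line (needs id + description)")
  ids <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate gene-set ID in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pathways <- lapply(fields, function(f) {
    gs <- unique(f[-(1:2)])
    gs <- gs[nzchar(gs)]
    list(pathway_id = f[1], description = f[2], gene_ids = gs)
  })
  empties <- vapply(pathways, function(p) length(p$gene_ids) == 0, logical(1))
  if (any(empties))
    warning("empty gene set(s) retained: ", paste(ids[empties], collapse = ", "))

  unresolved <- do.call(rbind, lapply(pathways, function(p) {
    m <- setdiff(p$gene_ids, genes$gene_id)
    if (!length(m)) return(NULL)
    data.frame(pathway_id = p$pathway_id, gene_id = m,
               stringsAsFactors = FALSE)
  }))
  if (is.null(unresolved))
    unresolved <- data.frame(pathway_id = character(), gene_id = character(),
                             stringsAsFactors = FALSE)
  list(genes = genes, pathways = pathways, unresolved = unresolved)
}

#' Write a gene BED file and a pathway GMT file
#'
#' Inverse of [read_gene_sets()] (1-based closed gene intervals written as
#' 0-based half-open BED records).
#'
#' @param genes data.frame with gene_id, chrom, start_bp, end_bp.
#' @param pathways list of lists with pathway_id, description, gene_ids.
#' @param bed_path,gmt_path output paths.
#' @return invisibly, `c(bed_path, gmt_path)`.
#' @export
write_gene_sets <- function(genes, pathways, bed_path, gmt_path) {
  utils::write.table(data.frame(genes$chrom, genes$start_bp - 1L,
                                genes$end_bp, genes$gene_id),
                     bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(vapply(pathways, function(p)
    paste(c(p$pathway_id, p$description, p$gene_ids), collapse = "\t"), ""),
    gmt_path)
  invisible(c(bed_path, gmt_path))
}
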