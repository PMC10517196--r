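#' Read target genotypes into a genotype matrix
#'
#' VCF input is parsed with \pkg{vcfR}; per-sample GT fields are converted
#' to alt-allele counts \{0, 1, 2\} (DS dosage used when GT is absent), with
#' `./.` mapped to missing. Multi-allelic and non-diploid records are
#' rejected with a warning and kept out of the matrix. The dosage-TSV
#' dialect has samples as rows, a `sample_id` column, a header of variant
#' IDs encoded `chrom:bp:ref:alt`, and `NA` for missing.
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage"`.
#' @return A [genotype_matrix()] with variants sorted by (chrom, bp).
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- as.character(fix[, "CHROM"])
  bp <- as.integer(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  id <- as.character(fix[, "ID"])
  fallback <- paste(chrom, bp, ref, alt, sep = ":")
  id[is.na(id) | id == "."] <- fallback[is.na(id) | id == "."]

  fmt <- v@gt[, "FORMAT"]
  has_gt <- all(grepl("(^|:)GT(:|$)", fmt))
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (!has_gt && !has_ds)
    stop("VCF lacks both GT and DS per-sample fields")
  if (has_gt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    alleles <- gsub("\\|", "/", gt)
    count1 <- function(x) {
      parts <- strsplit(x, "/", fixed = TRUE)
      vapply(parts, function(a) {
        if (length(a) != 2) return(NA_real_)  # non-diploid, flagged below
        if (any(a == "." | a == "")) return(NA_real_)
        sum(a == "1")
      }, numeric(1))
    }
    dos <- apply(alleles, 2, count1)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
    ploidy_bad <- apply(alleles, 1, function(r) {
      any(!is.na(r) & lengths(strsplit(r, "/", fixed = TRUE)) != 2)
    })
  } else {
    dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
    ploidy_bad <- rep(FALSE, nrow(dos))
  }
  multi <- grepl(",", alt, fixed = TRUE)
  drop <- multi | ploidy_bad
  if (any(drop))
    warning(sprintf("rejected %d VCF record(s): %d multi-allelic, %d non-diploid",
                    sum(drop), sum(multi), sum(ploidy_bad)))
  keep <- !drop
  genotype_matrix(t(dos[keep, , drop = FALSE]),
                  sample_ids = colnames(v@gt)[-1],
                  variants = data.frame(variant_id = id[keep],
                                        chrom = chrom[keep], bp = bp[keep],
                                        ref = ref[keep], alt = alt[keep],
                                        stringsAsFactors = FALSE))
}

read_genotypes_dosage <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (!"sample_id" %in% names(tab))
    stop("dosage TSV lacks sample_id column")
  ids <- tab$sample_id
  vids <- setdiff(names(tab), "sample_id")
  dos <- vapply(tab[vids], function(x) suppressWarnings(as.numeric(x)),
                numeric(nrow(tab)))
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(tab))
  parts <- strsplit(vids, ":", fixed = TRUE)
  if (any(lengths(parts) != 4))
    stop("dosage TSV variant headers must be chrom:bp:ref:alt")
  variants <- data.frame(variant_id = vids,
                         chrom = vapply(parts, `[`, "", 1),
                         bp = as.integer(vapply(parts, `[`, "", 2)),
                         ref = vapply(parts, `[`, "", 3),
                         alt = vapply(parts, `[`, "", 4),
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, sample_ids = ids, variants = variants)
}

#' Write a genotype matrix
#'
#' VCF output is plain-text VCFv4.2 with GT fields (only defined for
#' integer dosages; fractional dosages must use the dosage-TSV format).
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @param format `"vcf"` or `"dosage"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "dosage") {
    vid <- paste(G$variants$chrom, G$variants$bp, G$variants$ref,
                 G$variants$alt, sep = ":")
    tab <- data.frame(sample_id = G$sample_ids, check.names = FALSE)
    tab[vid] <- as.data.frame(G$dosage)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  d <- G$dosage
  if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE))
    stop("VCF GT output requires integer dosages; use format = 'dosage'")
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  ok <- !is.na(t(d))
  gt[ok] <- gt_code[round(t(d))[ok] + 1]
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", G$sample_ids), collapse = "\t"))
  body <- paste(G$variants$chrom, G$variants$bp, G$variants$variant_id,
                G$variants$ref, G$variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
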