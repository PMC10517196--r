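sumstats_for <- function(G, a1, a2, beta, p = NULL) {
  data.frame(variant_id = G$variants$variant_id, chrom = G$variants$chrom,
             bp = G$variants$bp, a1 = a1, a2 = a2, beta = beta,
             p = if (is.null(p)) rep(0.5, nrow(G$variants)) else p,
             stringsAsFactors = FALSE)
}

test_that("allele harmonization orients betas and drops ambiguous pairs", {
  d <- matrix(rbinom(40, 2, 0.4), 10, 4)
  G <- make_G(d, ref = c("G", "A", "A", "C"), alt = c("A", "G", "T", "G"))
  stats <- sumstats_for(G, a1 = c("A", "A", "A", "C"),
                        a2 = c("G", "G", "T", "A"),
                        beta = c(0.2, 0.2, 0.2, 0.2))
  w <- harmonize_weights(stats, G)
  # A1=A/A2=G vs ref=G/alt=A: effect allele is alt -> same, +0.2
  expect_equal(w$orientation[1], "same")
  expect_equal(w$beta_alt[1], 0.2)
  # A1=A/A2=G vs ref=A/alt=G: effect allele is ref -> flipped, -0.2
  expect_equal(w$orientation[2], "flipped")
  expect_equal(w$beta_alt[2], -0.2)
  # A/T palindromic: strand-ambiguous, dropped
  expect_equal(w$status[3], "ambiguous_dropped")
  expect_true(is.na(w$beta_alt[3]))
  # C/A against C/G target: allele mismatch
  expect_equal(w$status[4], "mismatch_dropped")
  expect_equal(as.integer(attr(w, "counts")),
               c(2L, 1L, 1L))
})

test_that("duplicate positions with conflicting alleles are dropped entirely", {
  G <- make_G(matrix(rbinom(20, 2, 0.4), 10, 2), bp = c(100L, 200L))
  stats <- rbind(sumstats_for(G, c("G", "G"), c("A", "A"), c(0.1, 0.2)),
                 data.frame(variant_id = "dup", chrom = "1", bp = 100L,
                            a1 = "C", a2 = "A", beta = 0.3, p = 0.5))
  expect_warning(w <- harmonize_weights(stats, G), "duplicate")
  expect_true(all(w$status[w$bp == 100] == "mismatch_dropped"))
  expect_equal(sum(w$status == "ok"), 1L)
})

test_that("P thresholding is boundary-inclusive", {
  G <- make_G(matrix(rbinom(30, 2, 0.4), 10, 3))
  w <- make_weights(G, p = c(0.001, 0.0011, 1))
  expect_equal(threshold_by_p(w, 0.001)$variant_id, "v001")
  expect_equal(nrow(threshold_by_p(w, 1)), 3L)
  expect_warning(threshold_by_p(w, 1e-9), "no SNPs")
})

test_that("APOE region exclude/only use closed bounds and partition", {
  bp <- c(44399999L, 44400000L, 45000000L, 46500000L, 46500001L)
  G <- make_G(matrix(rbinom(50, 2, 0.4), 10, 5), chrom = "19", bp = bp)
  w <- make_weights(G)
  region <- region_spec("19", 44400000L, 46500000L)
  excl <- exclude_region(w, region, "exclude")
  only <- exclude_region(w, region, "only")
  expect_setequal(excl$variant_id, c("v001", "v005"))
  expect_setequal(only$variant_id, c("v002", "v003", "v004"))
  # partition: disjoint and exhaustive
  expect_length(intersect(excl$variant_id, only$variant_id), 0L)
  expect_setequal(c(excl$variant_id, only$variant_id), w$variant_id)
  # other chromosome: retained under exclude, dropped under only
  G18 <- make_G(matrix(rbinom(10, 2, 0.4), 10, 1), chrom = "18",
                bp = 45000000L)
  w18 <- make_weights(G18)
  expect_equal(nrow(exclude_region(w18, region, "exclude")), 1L)
  expect_equal(nrow(exclude_region(w18, region, "only")), 0L)
})

test_that("pathway restriction intersects and commutes with thresholding", {
  G <- make_G(matrix(rbinom(100, 2, 0.4), 10, 10))
  w <- make_weights(G, p = seq(0.01, 0.1, 0.01))
  ps <- list(pathway_id = "P", snp_ids = c("v002", "v005", "v009"))
  r <- restrict_to_pathway(w, ps)
  expect_setequal(r$variant_id, ps$snp_ids)
  expect_warning(restrict_to_pathway(w, list(pathway_id = "Q",
                                             snp_ids = "zzz")), "no weights")
  a <- threshold_by_p(restrict_to_pathway(w, ps), 0.05)
  b <- restrict_to_pathway(threshold_by_p(w, 0.05), ps)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("greedy clumping keeps the best SNP per LD block", {
  # A (p=1e-5) clumps B (r2 ~ 0.3); C survives (r2 with A ~ 0.1)
  set.seed(31)
  d <- correlated_dosages(400, 3, rho = c(1, 0.62, 0.36), seed = 31)
  G <- make_G(d, bp = c(100000L, 200000L, 300000L))
  r2_ab <- cor(d[, 1], d[, 2])^2
  r2_ac <- cor(d[, 1], d[, 3])^2
  expect_gt(r2_ab, 0.2); expect_lt(r2_ac, 0.2)
  w <- make_weights(G, p = c(1e-5, 1e-4, 1e-3))
  got <- ld_clump(w, G, clump_spec())
  expect_equal(got$variant_id, c("v001", "v003"))
  # single SNP clumps to itself
  G1 <- make_G(matrix(rbinom(20, 2, 0.3), 20, 1))
  expect_equal(nrow(ld_clump(make_weights(G1), G1, clump_spec())), 1L)
})

test_that("the clumping window is a hard bound", {
  set.seed(32)
  base <- rbinom(200, 2, 0.4)
  d <- cbind(base, base)  # r2 = 1
  G <- make_G(d, bp = c(100000L, 700001L))  # 600 kb apart
  w <- make_weights(G, p = c(1e-5, 1e-3))
  got <- ld_clump(w, G, clump_spec(window_kb = 500))
  expect_equal(nrow(got), 2L)  # outside the window: never clumped
  got2 <- ld_clump(w, G, clump_spec(window_kb = 700))
  expect_equal(got2$variant_id, "v001")
})

test_that("clump output is invariant to input row order, with bp tie-break", {
  set.seed(33)
  for (rep in 1:10) {
    n <- 60; m <- 8
    d <- correlated_dosages(n, m, rho = runif(m, 0, 1), seed = 100 + rep)
    G <- make_G(d, bp = sort(sample(1:400000, m)))
    p <- sample(c(1e-4, 1e-3, 1e-3, 0.01, 0.05, 0.05, 0.2, 0.5))
    w <- make_weights(G, p = p)
    ref <- ld_clump(w, G, clump_spec())
    shuf <- ld_clump(w[sample(m), ], G, clump_spec())
    expect_identical(ref$variant_id, shuf$variant_id)
  }
})

test_that("zero-variance variants cannot clump anything", {
  set.seed(34)
  d <- cbind(rep(1, 50), rbinom(50, 2, 0.4))
  G <- make_G(d, bp = c(1000L, 2000L))
  w <- make_weights(G, p = c(1e-6, 1e-3))  # constant SNP is the first index
  got <- ld_clump(w, G, clump_spec())
  expect_equal(nrow(got), 2L)
})

test_that("scores are exact weighted sums with mean-imputed missingness", {
  G <- make_G(matrix(c(0, 1, 2), 1, 3))
  w <- make_weights(G, beta = c(0.1, -0.2, 0.3))
  expect_equal(unname(compute_prs(G, w)), 0.4, ignore_attr = TRUE)
  # all-zero betas give zero scores
  expect_equal(unname(compute_prs(G, make_weights(G, beta = c(0, 0, 0)))),
               0, ignore_attr = TRUE)
  # missing dosage imputed as 2 x alt frequency: af 0.25 -> 0.5 * 0.4 = 0.2
  d <- matrix(c(NA, 1, 1, 0, 0), 5, 1)
  Gm <- make_G(d)
  wm <- make_weights(Gm, beta = 0.4)
  sc <- compute_prs(Gm, wm, "mean_impute")
  expect_equal(unname(sc[1]), 2 * 0.25 * 0.4)
  expect_equal(unname(compute_prs(Gm, wm, "omit")[1]), 0)
  # empty weight list: all-missing column, n_snps_used 0
  e <- compute_prs(G, w[0, ])
  expect_true(all(is.na(e)))
  expect_equal(attr(e, "n_snps_used"), 0L)
})

test_that("n_snps_used is non-decreasing in the P threshold", {
  set.seed(35)
  cfg <- sim_config(seed = 35, n_target = 150, n_discovery = 300,
                    n_snps = 100, n_genes = 10, block_size = 5,
                    missing_rate = 0,
                    pathways = list(list(pathway_id = "pw1",
                                         description = "one", genes = 1:3,
                                         effect_mean = 0.05,
                                         effect_sd = 0.02)),
                    rois = data.frame(name = "roi1", family = "cortical",
                                      mu = 2.5, scale = 0.15,
                                      pathway_id = "pw1", sign = -1,
                                      effect_size = 0.15))
  G <- simulate_genotypes(cfg, "target")
  stats <- simulate_discovery_sumstats(cfg)
  w <- harmonize_weights(stats, G)
  st <- build_score_matrix(G, w, list(), clump_spec(),
                           region_spec("19", 44400000L, 46500000L),
                           apoe_modes = "with_apoe")
  meta <- st$meta[order(st$meta$threshold), ]
  expect_true(all(diff(meta$n_snps_used) >= 0))
})

test_that("flipping a variant's ref/alt leaves associations unchanged", {
  set.seed(36)
  cfg <- sim_config(seed = 36, n_target = 200, n_discovery = 400,
                    n_snps = 50, n_genes = 5, block_size = 5,
                    missing_rate = 0,
                    pathways = list(list(pathway_id = "pw1",
                                         description = "one", genes = 1:2,
                                         effect_mean = 0.05,
                                         effect_sd = 0.02)),
                    rois = data.frame(name = "roi1", family = "cortical",
                                      mu = 2.5, scale = 0.15,
                                      pathway_id = "pw1", sign = -1,
                                      effect_size = 0.15))
  G <- simulate_genotypes(cfg, "target")
  stats <- simulate_discovery_sumstats(cfg)
  w1 <- harmonize_weights(stats, G)
  s1 <- compute_prs(G, threshold_by_p(w1, 0.5))

  # flip variants 3 and 7 in the target: d -> 2 - d, ref/alt swapped
  G2 <- G
  for (j in c(3, 7)) {
    G2$dosage[, j] <- 2 - G2$dosage[, j]
    tmp <- G2$variants$ref[j]
    G2$variants$ref[j] <- G2$variants$alt[j]
    G2$variants$alt[j] <- tmp
  }
  w2 <- harmonize_weights(stats, G2)
  s2 <- compute_prs(G2, threshold_by_p(w2, 0.5))
  # scores differ by a constant offset only
  expect_lt(diff(range((s2 - s1))), 1e-10)
  # downstream association identical
  y <- 0.3 * s1 + rnorm(length(s1))
  f1 <- fit_association(y, unname(s1), NULL)
  f2 <- fit_association(y, unname(s2), NULL)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$se, f2$se, tolerance = 1e-8)
  expect_equal(f1$p, f2$p, tolerance = 1e-8)
})

test_that("the score grid enumerates label x threshold x mode columns", {
  set.seed(37)
  cfg <- sim_config(seed = 37, n_target = 150, n_discovery = 300,
                    n_snps = 100, n_genes = 10, block_size = 5,
                    missing_rate = 0,
                    pathways = list(list(pathway_id = "pw1",
                                         description = "one",
                                         genes = 1:3, effect_mean = 0.05,
                                         effect_sd = 0.02)),
                    rois = data.frame(name = "roi1", family = "cortical",
                                      mu = 2.5, scale = 0.15,
                                      pathway_id = "pw1", sign = -1,
                                      effect_size = 0.15))
  G <- simulate_genotypes(cfg, "target")
  stats <- simulate_discovery_sumstats(cfg)
  ann <- simulate_annotation(cfg)
  m <- map_snps_to_genes(G$variants, ann$genes, 0)
  apoe <- region_spec("19", 40000001L, 40100000L)  # inside the layout
  ps <- build_pathway_snp_sets(ann$pathways, m, G$variants,
                               stats$variant_id, apoe)
  w <- harmonize_weights(stats, G)
  st <- build_score_matrix(G, w, ps, clump_spec(p_thresholds = 0.5,
                                                primary_threshold = 0.5),
                           apoe, apoe_modes = c("with_apoe", "no_apoe"))
  # (genome_wide + 1 pathway) x 1 threshold x 2 modes = 4 columns
  expect_equal(nrow(st$meta), 4L)
  expect_setequal(st$meta$score_label, c("genome_wide", "pw1"))
  # apoe_only uses exactly the region's SNPs pre-clump
  st2 <- build_score_matrix(G, w, list(), clump_spec(p_thresholds = 1,
                                                     primary_threshold = 1),
                            apoe, apoe_modes = "apoe_only")
  region_ids <- G$variants$variant_id[
    G$variants$chrom == apoe$chrom & G$variants$bp >= apoe$start_bp &
      G$variants$bp <= apoe$end_bp]
  expect_lte(st2$meta$n_snps_used, length(region_ids))
  expect_gt(st2$meta$n_snps_used, 0L)
})
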