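# Shared fixture builders and independent reference implementations.
# The references deliberately use naive formulations (explicit loops,
# full correlation matrices, literal textbook formulas) so they stay
# independent of the package's code paths.

make_G <- function(dosage, chrom = "1", bp = NULL, ref = "A", alt = "G") {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  genotype_matrix(dosage,
                  sample_ids = sprintf("s%03d", seq_len(nrow(dosage))),
                  variants = data.frame(
                    variant_id = sprintf("v%03d", seq_len(m)),
                    chrom = rep(chrom, length.out = m), bp = bp,
                    ref = rep(ref, length.out = m),
                    alt = rep(alt, length.out = m),
                    stringsAsFactors = FALSE))
}

make_weights <- function(G, beta = NULL, p = NULL) {
  m <- nrow(G$variants)
  data.frame(variant_index = seq_len(m),
             variant_id = G$variants$variant_id,
             chrom = G$variants$chrom, bp = G$variants$bp,
             beta_alt = if (is.null(beta)) rep(0.1, m) else beta,
             p = if (is.null(p)) rep(0.5, m) else p,
             orientation = "same", status = "ok",
             stringsAsFactors = FALSE)
}

# Naive greedy clumping over a precomputed full r^2 matrix.
brute_clump <- function(weights, G, r2_max, window_kb) {
  w <- weights[weights$status == "ok", , drop = FALSE]
  r2m <- suppressWarnings(
    stats::cor(G$dosage, use = "pairwise.complete.obs"))^2
  r2m[is.na(r2m)] <- 0
  remaining <- seq_len(nrow(w))
  picked <- integer()
  while (length(remaining)) {
    ps <- w$p[remaining]
    best <- remaining[order(ps, w$bp[remaining])][1]
    picked <- c(picked, best)
    remaining <- setdiff(remaining, best)
    drop <- c()
    for (j in remaining) {
      if (w$chrom[j] == w$chrom[best] &&
          abs(w$bp[j] - w$bp[best]) <= window_kb * 1000 &&
          r2m[w$variant_index[best], w$variant_index[j]] > r2_max)
        drop <- c(drop, j)
    }
    remaining <- setdiff(remaining, drop)
  }
  sort(w$variant_id[picked])
}

# Literal BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, via loops.
bh_ref <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) p[o[j]] * m / j)
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Normal-equations OLS for the score coefficient: (X'X)^-1 X'y.
ols_ref <- function(y, s, X = NULL) {
  M <- cbind(1, s, if (!is.null(X)) as.matrix(X))
  bhat <- solve(crossprod(M), crossprod(M, y))
  res <- y - M %*% bhat
  df <- length(y) - ncol(M)
  sigma2 <- sum(res^2) / df
  vcv <- sigma2 * solve(crossprod(M))
  tval <- bhat[2] / sqrt(vcv[2, 2])
  list(beta = bhat[2], se = sqrt(vcv[2, 2]),
       p = 2 * stats::pt(-abs(tval), df))
}

# Dosage columns with a target correlation to a base column, by mixing.
correlated_dosages <- function(n, k, rho, seed) {
  set.seed(seed)
  z0 <- stats::rnorm(n)
  sapply(seq_len(k), function(i) {
    z <- rho[i] * z0 + sqrt(1 - rho[i]^2) * stats::rnorm(n)
    as.numeric(cut(z, stats::qnorm(c(0, 0.25, 0.75, 1)))) - 1
  })
}
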