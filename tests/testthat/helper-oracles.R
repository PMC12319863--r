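# Independent first-principles oracles and small fixture builders.
# These deliberately use explicit loops / definitions, never the package's
# own code paths.

# random symmetric dissimilarity matrix over the 8 body-part conditions
random_rdm <- function(seed, n = 8) {
  set.seed(seed)
  M <- matrix(stats::runif(n * n, 0, 2), n)
  D <- (M + t(M)) / 2
  diag(D) <- 0
  rownames(D) <- colnames(D) <- body_part_conditions()[seq_len(n)]
  D
}

# ANOSIM R from its definition, with explicit pair loops
oracle_anosim_r <- function(D, partition) {
  n <- nrow(D)
  d <- c(); within <- c()
  for (j in 1:(n - 1)) for (i in (j + 1):n) {
    d <- c(d, D[i, j])
    within <- c(within, partition[i] == partition[j])
  }
  rk <- rank(d)
  M <- length(d)
  (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}

# Pearson correlation of the off-diagonal dissimilarities, explicit loop
oracle_mantel_r <- function(D1, D2) {
  v1 <- c(); v2 <- c()
  n <- nrow(D1)
  for (j in 1:(n - 1)) for (i in (j + 1):n) {
    v1 <- c(v1, D1[i, j]); v2 <- c(v2, D2[i, j])
  }
  stats::cor(v1, v2)
}

# Spearman rho as Pearson on average ranks
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# balanced two-way ANOVA by hand-computed sums of squares
oracle_anova_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  gm <- mean(y)
  ssa <- sum(tapply(y, a, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, b, function(v) length(v) * (mean(v) - gm)^2))
  cells <- tapply(y, list(a, b), mean)
  counts <- table(a, b)
  sscells <- sum(counts * (cells - gm)^2)
  ssab <- sscells - ssa - ssb
  sse <- sum((y - ave(y, a, b))^2)
  dfa <- nlevels(a) - 1; dfb <- nlevels(b) - 1
  dfab <- dfa * dfb
  dfe <- length(y) - nlevels(a) * nlevels(b)
  list(F_a = (ssa / dfa) / (sse / dfe),
       F_b = (ssb / dfb) / (sse / dfe),
       F_ab = (ssab / dfab) / (sse / dfe),
       ss = c(a = ssa, b = ssb, ab = ssab, e = sse))
}

# tiny strongly clustered noiseless cohort config for geometry tests
clustered_config <- function(seed = 42, n_voxels = 40, n_per_group = 2,
                             run_noise_sd = 0) {
  cohort_config(n_per_group = n_per_group, n_voxels = n_voxels,
                category_separation = 5, condition_separation = 1,
                run_noise_sd = run_noise_sd, seed = seed)
}

# pattern set with exactly separable categories and no noise
separable_patterns <- function(seed = 1, n_voxels = 12) {
  cfg <- cohort_config(n_per_group = 1, n_voxels = n_voxels,
                       category_separation = 10, condition_separation = 0.5,
                       run_noise_sd = 0, seed = seed)
  generate_pattern_set(cfg, 1)
}

# pure-noise pattern set (no category structure at all)
noise_patterns <- function(seed, n_voxels = 30) {
  cfg <- cohort_config(n_per_group = 1, n_voxels = n_voxels,
                       category_separation = 0, condition_separation = 0,
                       run_noise_sd = 1, seed = seed)
  generate_pattern_set(cfg, 1)
}
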