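test_that("partition enumeration counts and structure", {
  m <- enumerate_partitions()
  expect_equal(nrow(m), 420)
  expect_equal(colnames(m), body_part_conditions())
  # every model assigns each condition exactly once with the right sizes
  sizes <- t(apply(m, 1, function(r) as.integer(table(
    factor(r, levels = c("effector", "face", "non-effector"))))))
  expect_true(all(sizes[, 1] == 4 & sizes[, 2] == 2 & sizes[, 3] == 2))
  expect_false(any(duplicated(apply(m, 1, paste, collapse = "|"))))
  # hypothesized model is row 1 and appears exactly once
  hyp <- hypothesized_partition()[colnames(m)]
  hits <- apply(m, 1, function(r) all(r == hyp))
  expect_equal(which(hits), 1L)
  # small case oracle: 4 items, sizes (2,1,1) -> 4!/2! = 12 models
  m4 <- enumerate_partitions(items = letters[1:4], sizes = c(2, 1, 1),
                             labels = c("x", "y", "z"),
                             hypothesized = NULL)
  expect_equal(nrow(m4), 12)
})

test_that("ANOSIM R: toy cases and 100-fixture oracle equivalence", {
  # toy 4-sample 2-group case with within ranks {1,2}, between {3,4,5,6}
  D <- matrix(0, 4, 4)
  D[2, 1] <- D[1, 2] <- 0.1          # within group 1
  D[4, 3] <- D[3, 4] <- 0.2          # within group 2
  D[3, 1] <- D[1, 3] <- 0.5
  D[4, 1] <- D[1, 4] <- 0.6
  D[3, 2] <- D[2, 3] <- 0.7
  D[4, 2] <- D[2, 4] <- 0.8
  expect_equal(anosim_r(D, c("g1", "g1", "g2", "g2")), 1)
  # all dissimilarities equal -> R = 0
  E <- matrix(1, 8, 8); diag(E) <- 0
  expect_equal(anosim_r(E, hypothesized_partition()), 0)
  # random fixtures vs the first-principles oracle
  set.seed(606)
  models <- enumerate_partitions()
  for (i in 1:100) {
    D <- random_rdm(i + 1000)
    part <- models[sample(420, 1), rownames(D)]
    expect_equal(anosim_r(D, part), oracle_anosim_r(D, part),
                 tolerance = 1e-12)
  }
})

test_that("anosim_r agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  for (i in 1:5) {
    D <- random_rdm(i + 50)
    part <- hypothesized_partition()[rownames(D)]
    ref <- vegan::anosim(as.dist(D), grouping = factor(part),
                         permutations = 19)
    expect_equal(anosim_r(D, part), unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("exhaustive ANOSIM test: null size, twins, minimum p", {
  D <- random_rdm(7)
  res <- anosim_test(D)
  expect_length(res$null, 420)
  expect_equal(res$R, res$null[1])
  expect_gte(res$p, 1 / 420)
  # rank invariance under strictly monotone transforms
  D2 <- D^3
  res2 <- anosim_test(D2)
  expect_equal(res2$null, res$null, tolerance = 1e-12)
  # the 420 null values pair into 210 equal twins (size-2 label swap)
  models <- enumerate_partitions()
  key <- apply(models, 1, function(r)
    paste(paste(sort(names(r)[r == "effector"]), collapse = ","),
          paste(sort(c(paste(sort(names(r)[r == "face"]), collapse = ","),
                       paste(sort(names(r)[r == "non-effector"]),
                             collapse = ","))), collapse = " | "),
          sep = " / "))
  expect_equal(length(unique(key)), 210)
  for (k in unique(key)[1:25]) {
    twins <- res$null[key == k]
    expect_length(twins, 2)
    expect_equal(twins[1], twins[2], tolerance = 1e-12)
  }
})

test_that("Mantel test: identity, affine invariance, oracle r, schemes", {
  D <- random_rdm(8); D2 <- random_rdm(9)
  self <- mantel_test(D, D)
  expect_equal(self$r, 1, tolerance = 1e-12)
  aff <- mantel_test(D, 2.5 * D + 0.3)
  expect_equal(aff$r, 1, tolerance = 1e-12)
  res <- mantel_test(D, D2)
  expect_equal(res$r, oracle_mantel_r(D, D2), tolerance = 1e-12)
  expect_equal(res$n_permutations, factorial(8))
  # r is symmetric in its arguments
  expect_equal(res$r, mantel_test(D2, D)$r, tolerance = 1e-12)
  # simultaneous identical relabeling leaves r and p unchanged
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  Dp <- D[perm, perm]; D2p <- D2[perm, perm]
  rownames(Dp) <- colnames(Dp) <- rownames(D)
  rownames(D2p) <- colnames(D2p) <- rownames(D)
  resp <- mantel_test(Dp, D2p)
  expect_equal(resp$r, res$r, tolerance = 1e-12)
  expect_equal(resp$p, res$p, tolerance = 1e-12)
  # Monte-Carlo p converges to the complete-enumeration p
  mc <- mantel_test(D, D2, scheme = "monte_carlo", n_mc = 20000, seed = 3)
  expect_lt(abs(mc$p - res$p), 3 * sqrt(res$p * (1 - res$p) / 20000) + 1e-3)
  # constant matrix errors
  E <- matrix(1, 8, 8); diag(E) <- 0
  rownames(E) <- colnames(E) <- rownames(D)
  expect_error(mantel_test(D, E), "constant")
})

test_that("Mantel r agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  D <- random_rdm(31); D2 <- random_rdm(32)
  ref <- vegan::mantel(as.dist(D), as.dist(D2), permutations = 19)
  expect_equal(mantel_test(D, D2)$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("within/between similarity: shared geometry gives null effects", {
  # all subjects share one RDM plus tiny jitter -> within ~ between
  set.seed(21)
  base <- random_rdm(77)
  rdms <- lapply(1:10, function(i) {
    J <- matrix(rnorm(64, sd = 1e-3), 8)
    D <- base + (J + t(J)) / 2
    diag(D) <- 0
    rownames(D) <- colnames(D) <- rownames(base)
    class(D) <- c("rdm", "matrix", "array")
    D
  })
  groups <- rep(c("TD-like", "ASD-like"), each = 5)
  res <- within_between_similarity(rdms, groups)
  expect_equal(nrow(res$table), 20)
  expect_equal(res$table$z, atanh(res$table$r), tolerance = 1e-12)
  dz <- abs(mean(res$table$z[res$table$type == "within"]) -
              mean(res$table$z[res$table$type == "between"]))
  expect_lt(dz, 0.05)
  expect_gt(res$anova$A$p, 0.05)
})

test_that("distinct group geometries raise within above between", {
  cfgA <- cohort_config(6, 30, category_separation = 2, run_noise_sd = 1,
                        seed = 41)
  rdms <- lapply(generate_cohort(cfgA), compute_split_half_rdm)
  # overwrite the ASD-like half with a different generative geometry
  cfgB <- cohort_config(6, 30, category_separation = 0,
                        condition_separation = 2, run_noise_sd = 1, seed = 140)
  rdmsB <- lapply(generate_cohort(cfgB)[7:12], compute_split_half_rdm)
  rdms[7:12] <- rdmsB
  groups <- rep(c("TD-like", "ASD-like"), each = 6)
  res <- within_between_similarity(rdms, groups)
  zt <- tapply(res$table$z, res$table$type, mean)
  expect_gt(zt["within"], zt["between"])
})

test_that("trait correlations: monotone traits and missing-value handling", {
  r_vals <- seq(0.1, 0.9, length.out = 12)
  traits <- data.frame(subject = 1:12,
                       up = r_vals^2 + 1,
                       down = -3 * r_vals,
                       flat = rep(2, 12))
  res <- trait_correlations(r_vals, traits, family = 16)
  expect_equal(res$rho[res$trait == "up"], 1)
  expect_equal(res$rho[res$trait == "down"], -1)
  expect_true(is.na(res$rho[res$trait == "flat"]))
  expect_equal(res$p_bonferroni, pmin(1, res$p * 16), tolerance = 1e-12)
})

test_that("mean subject ANOSIM R rises with category separation", {
  seps <- c(0, 1, 4)
  mr <- vapply(seps, function(s) {
    cfg <- cohort_config(6, 30, category_separation = s,
                         condition_separation = 0.5, run_noise_sd = 1,
                         seed = 11)
    mean(subject_anosim_r(lapply(generate_cohort(cfg),
                                 compute_split_half_rdm)))
  }, numeric(1))
  expect_true(all(diff(mr) > 0))
  expect_gt(mr[3], 0.9)
})
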