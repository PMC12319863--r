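test_that("run design follows the block/baseline schedule", {
  d <- build_run_design()
  expect_equal(nrow(d$blocks), 20)
  expect_true(all(table(d$blocks$condition) == 2))
  expect_equal(d$block_length, 12)
  expect_equal(d$total_duration, 318)
  expect_equal(d$n_volumes, 106)
  expect_equal(d$blocks$onset[1], 27)
  # gaps between consecutive blocks: 12 s blocks, baselines after 5/10/15
  gaps <- diff(d$blocks$onset)
  expect_equal(gaps[c(5, 10, 15)], rep(24, 3))
  expect_equal(gaps[-c(5, 10, 15)], rep(12, 16))
  expect_error(build_run_design(rep(bodygeom_conditions()[1], 20)),
               "exactly twice")
  expect_error(build_run_design(TR = 7), "whole number")
})

test_that("default block orders are valid for several runs", {
  for (r in 1:4) {
    ord <- default_block_order(r)
    expect_true(all(table(ord) == 2))
    expect_false(any(ord[-1] == ord[-20]))  # no immediate repeats
  }
})

test_that("canonical HRF shape: zero onset, peak near 5 s, sample count", {
  h <- canonical_hrf()
  expect_equal(h$values[1], 0)
  expect_equal(h$t[which.max(h$values)], 5, tolerance = 0.2)
  expect_length(h$values, 32 / 0.1 + 1)
  expect_equal(max(h$values), 1)
  expect_lt(min(h$values), 0)   # undershoot present
  expect_error(canonical_hrf(length = 3), "exceed the response delay")
})

test_that("design matrix: convolution matches a direct discrete oracle", {
  d <- build_run_design()
  h <- canonical_hrf()
  X <- build_design_matrix(d, hrf = h, highpass_cutoff = Inf)
  cond <- d$blocks$condition[1]
  # direct convolution oracle on the microtime grid
  dt <- h$dt
  n_fine <- round(d$total_duration / dt)
  t_fine <- (seq_len(n_fine) - 1) * dt
  box <- numeric(n_fine)
  for (o in d$blocks$onset[d$blocks$condition == cond])
    box[t_fine >= o & t_fine < o + 12] <- 1
  reg <- numeric(n_fine)
  for (k in which(box > 0)) {
    span <- k:min(n_fine, k + length(h$values) - 1)
    reg[span] <- reg[span] + h$values[seq_along(span)]
  }
  vol_idx <- round(((seq_len(d$n_volumes) - 1) * d$TR) / dt) + 1
  expect_equal(unname(X[, cond]), reg[vol_idx], tolerance = 1e-8)
})

test_that("design matrix layout: DCT count, constant last, motion columns", {
  d <- build_run_design()
  X <- build_design_matrix(d)
  expect_equal(sum(grepl("^dct", colnames(X))), floor(2 * 318 / 128))
  expect_equal(colnames(X)[ncol(X)], "constant")
  expect_true(all(X[, "constant"] == 1))
  mot <- generate_motion_params(d$n_volumes, amplitude = 0.1, seed = 1)
  Xm <- build_design_matrix(d, motion = mot)
  expect_equal(sum(grepl("^motion", colnames(Xm))), 6)
  expect_error(build_design_matrix(d, highpass_cutoff = 5), "2 x TR")
  expect_error(build_design_matrix(d, motion = mot[-1, ]), "n_volumes")
})

test_that("GLM recovers known betas noiselessly and forms contrasts", {
  d <- build_run_design()
  X <- build_design_matrix(d, highpass_cutoff = Inf)
  set.seed(9)
  B <- matrix(rnorm(ncol(X) * 5), ncol(X), 5,
              dimnames = list(colnames(X), NULL))
  Y <- X %*% B
  fit <- fit_glm(Y, X)
  expect_equal(fit$beta, B, tolerance = 1e-9)
  con <- contrast_estimate(fit, c(`whole body` = 1, chair = -1))
  expect_equal(con, B["whole body", ] - B["chair", ], tolerance = 1e-9)
  expect_equal(fit$df, nrow(X) - qr(X)$rank)
})

test_that("condition betas are invariant to adding high-pass columns", {
  d <- build_run_design()
  X0 <- build_design_matrix(d, highpass_cutoff = Inf)
  X1 <- build_design_matrix(d, highpass_cutoff = 128)
  set.seed(10)
  B <- matrix(rnorm(ncol(X1) * 3), ncol(X1), 3,
              dimnames = list(colnames(X1), NULL))
  Y <- X1 %*% B   # signal includes drift spanned by the DCT basis
  conds <- bodygeom_conditions()
  f1 <- fit_glm(Y, X1)
  expect_equal(f1$beta[conds, ], B[conds, ], tolerance = 1e-8)
})

test_that("pooled AR(1) estimate recovers the simulated coefficient", {
  # long series, low-dimensional design: estimator consistency
  set.seed(3)
  n <- 5000
  X <- cbind(reg = rnorm(n), constant = 1)
  E <- vapply(1:10, function(v)
    as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - 0.3^2)), 0.3,
                             method = "recursive")), numeric(n))
  Y <- X %*% matrix(rnorm(20), 2, 10) + E
  fit <- fit_glm(Y, X, whiten = TRUE)
  expect_lt(abs(fit$ar1 - 0.3), 0.03)
  # pooled estimate agrees with a per-voxel Yule-Walker oracle at run length
  d <- build_run_design()
  cfg <- cohort_config(n_per_group = 1, n_voxels = 25,
                       category_separation = 1, run_noise_sd = 0, seed = 2)
  ps <- generate_pattern_set(cfg, 1)
  ys <- generate_timeseries(ps, d, ar_coefficient = 0.3, noise_sd = 1,
                            seed = 3)
  Xr <- attr(ys, "design_matrices")[[1]]
  fit_run <- fit_glm(ys[[1]], Xr, whiten = TRUE)
  f0 <- fit_glm(ys[[1]], Xr)
  r <- ys[[1]] - Xr %*% f0$beta
  yw <- mean(apply(r, 2, function(e)
    sum(e[-1] * e[-length(e)]) / sum(e^2)))
  expect_lt(abs(fit_run$ar1 - yw), 0.02)
})

test_that("rank-deficient designs are flagged and pseudo-solved", {
  X <- cbind(1, 1:10, (1:10) * 2)
  colnames(X) <- c("a", "b", "c")
  expect_warning(fit <- fit_glm(matrix(rnorm(10)), X), "rank-deficient")
  expect_true(fit$rank_deficient)
  expect_true(all(is.finite(fit$beta)))
})

test_that("group t-maps: closed form, identical groups, null calibration", {
  set.seed(11)
  C <- matrix(0.5 + rnorm(40 * 6, sd = 1e-6), 40, 6)
  tm <- group_t_map(C, mode = "one-sample")
  expect_equal(tm$t, colMeans(C) / (apply(C, 2, sd) / sqrt(40)),
               tolerance = 1e-9)
  G <- matrix(rnorm(20 * 8), 20, 8)
  tm2 <- group_t_map(G, G, mode = "two-sample")
  expect_true(all(abs(tm2$t) < 1e-9))
  # type-I calibration at p < 0.01 (one-sided uncorrected)
  set.seed(12)
  null_c <- matrix(rnorm(30 * 4000), 30, 4000)
  frac <- mean(group_t_map(null_c, mode = "one-sample")$mask)
  expect_lt(abs(frac - 0.01), 0.005)
  Z <- matrix(1, 5, 3)
  expect_warning(tm3 <- group_t_map(Z, mode = "one-sample"), "zero-variance")
  expect_true(all(is.na(tm3$t)))
})
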