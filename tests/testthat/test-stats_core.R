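test_that("welch_t matches t.test and reproduces summary-statistic inputs", {
  set.seed(101)
  for (i in 1:30) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    ours <- welch_t_data(x, y)
    ref <- t.test(x, y)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # equal means, equal everything -> t = 0
  expect_equal(welch_t(5, 1, 10, 5, 2, 12)$statistic, 0)
  expect_error(welch_t(1, 0, 5, 1, 0, 5), "zero pooled variance")
})

test_that("cohens_d follows the pooled-SD definition and scale property", {
  expect_equal(cohens_d(5, 1, 10, 5, 2, 12), 0)
  d1 <- cohens_d(3, 1.5, 20, 1, 2.5, 20)
  expect_equal(d1, (3 - 1) / sqrt((1.5^2 + 2.5^2) / 2), tolerance = 1e-12)
  expect_equal(cohens_d(3, 3, 20, 1, 5, 20), d1 / 2, tolerance = 1e-12)
  expect_error(cohens_d(1, 0, 5, 2, 0, 5), "zero pooled SD")
})

test_that("chi_square_2x2 matches chisq.test on random tables", {
  set.seed(202)
  for (i in 1:100) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    s1 <- sample(1:(n1 - 1), 1); s2 <- sample(1:(n2 - 1), 1)
    ours <- chi_square_2x2(s1, n1, s2, n2)
    tab <- matrix(c(s1, n1 - s1, s2, n2 - s2), 2, byrow = TRUE)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$effect_size, sqrt(ours$statistic / (n1 + n2)),
                 tolerance = 1e-12)
  }
  expect_equal(chi_square_2x2(10, 20, 15, 30)$statistic, 0, tolerance = 1e-12)
  expect_error(chi_square_2x2(0, 10, 0, 10), "empty margin")
})

test_that("two_way_anova matches hand-computed sums of squares", {
  set.seed(303)
  for (i in 1:20) {
    a <- rep(c("a1", "a2"), each = 12)
    b <- rep(rep(c("b1", "b2", "b3"), each = 4), 2)
    y <- rnorm(24) + as.numeric(factor(a)) * runif(1) +
      as.numeric(factor(b)) * runif(1)
    ours <- two_way_anova(y, a, b)
    ref <- oracle_anova_ss(y, a, b)
    expect_equal(ours$A$statistic, ref$F_a, tolerance = 1e-8)
    expect_equal(ours$B$statistic, ref$F_b, tolerance = 1e-8)
    expect_equal(ours$`A:B`$statistic, ref$F_ab, tolerance = 1e-8)
    expect_equal(ours$A$partial_eta2, ref$ss["a"] / (ref$ss["a"] + ref$ss["e"]),
                 ignore_attr = TRUE, tolerance = 1e-8)
  }
  # identical cell means with within-cell spread -> all F = 0 exactly
  a <- rep(c("a1", "a2"), each = 12)
  b <- rep(rep(c("b1", "b2", "b3"), each = 4), 2)
  y0 <- rep(c(-1, 0, 1, 2), times = 6)   # same values in every cell
  flat <- two_way_anova(y0, a, b)
  expect_lt(flat$A$statistic, 1e-10)
  expect_lt(flat$B$statistic, 1e-10)
  expect_lt(flat$`A:B`$statistic, 1e-10)
})

test_that("mixed-design ANOVA uses subject error strata", {
  set.seed(304)
  subj <- rep(1:10, each = 2)
  type <- rep(c("within", "between"), 10)
  grp <- c(rep("g1", 5), rep("g2", 5))[subj]
  y <- rnorm(20) + (type == "within") * 0.5
  res <- two_way_anova(y, type, grp, design = "mixed", subject = subj)
  expect_false(is.null(res$A))
  expect_true(res$A$df[2] < 18)  # within-subject stratum, not pooled residual
  expect_true(res$A$p <= 1 && res$A$p > 0)
  expect_error(two_way_anova(y, type, grp, design = "mixed"),
               "requires 'subject'")
})

test_that("fisher_z is atanh with domain checks", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), atanh(0.9))
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("spearman_bonferroni matches rank-based oracle, handles ties", {
  set.seed(404)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- sample(1:8, n, replace = TRUE)   # plenty of ties
    y <- sample(1:8, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    ours <- spearman_bonferroni(x, y, family = 16)
    expect_equal(ours$statistic, oracle_spearman(x, y), tolerance = 1e-10)
    expect_equal(ours$p_corrected, min(1, ours$p * 16), tolerance = 1e-12)
  }
  expect_equal(spearman_bonferroni(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman_bonferroni(1:10, -(1:10)^3)$statistic, -1)
  expect_warning(res <- spearman_bonferroni(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$statistic))
})

test_that("framewise displacement follows the translation + rotation formula", {
  m <- matrix(0, 5, 6)
  expect_equal(framewise_displacement(m)$mean_fd, 0)
  m2 <- m; m2[3, 1] <- 1                       # single 1 mm x step
  fd <- framewise_displacement(m2)$fd
  expect_equal(fd[3], 1)
  expect_equal(fd[4], 1)                        # step back down
  m3 <- m; m3[2, 4] <- 0.02                     # 0.02 rad at 50 mm radius
  expect_equal(framewise_displacement(m3)$fd[2], 1)
})

test_that("one_sample_t closed form and sign conventions", {
  v <- c(1, 2, 3)
  res <- one_sample_t(v, 0)
  expect_equal(res$statistic, mean(v) / (sd(v) / sqrt(3)), tolerance = 1e-12)
  ref <- t.test(v, mu = 0)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(sign(res$statistic), sign(res$effect_size))
  expect_equal(one_sample_t(c(-1, 1, -2, 2), 0)$statistic, 0)
  expect_error(one_sample_t(rep(3, 4), 0), "zero variance")
})

test_that("welch_t type-I error calibrates to alpha under the null", {
  set.seed(505)
  rej <- mean(replicate(400, welch_t_data(rnorm(15), rnorm(15))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.03)
})
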