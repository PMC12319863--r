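#' Welch's unequal-variance t-test from summary statistics
#'
#' Computes Welch's t with the Welch-Satterthwaite degrees of freedom from
#' group means, standard deviations and sizes, so that statistics printed in a
#' demographics table (mean +/- SD, n per group) can be recomputed directly.
#' For raw data see [welch_t_data()].
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return A `stat_result` list: `statistic` (t), `df` (fractional), `p`
#'   (two-sided), `effect_size` (Cohen's d, pooled-SD convention).
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  for (v in c("mean1", "sd1", "n1", "mean2", "sd2", "n2"))
    .check_scalar(get(v), v)
  if (n1 < 2 || n2 < 2) .stopf("both group sizes must be >= 2")
  if (sd1 < 0 || sd2 < 0) .stopf("standard deviations must be >= 0")
  se2_1 <- sd1^2 / n1
  se2_2 <- sd2^2 / n2
  if (se2_1 + se2_2 <= 0) .stopf("zero pooled variance: t undefined")
  t_val <- (mean1 - mean2) / sqrt(se2_1 + se2_2)
  df <- (se2_1 + se2_2)^2 /
    (se2_1^2 / (n1 - 1) + se2_2^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t_val), df, lower.tail = FALSE)
  stat_result(statistic = t_val, df = df, p = p,
              effect_size = cohens_d(mean1, sd1, n1, mean2, sd2, n2),
              method = "Welch two-sample t")
}

#' @rdname welch_t
#' @param x,y raw observation vectors for the two groups.
#' @export
welch_t_data <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  welch_t(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

#' Cohen's d from summary statistics
#'
#' d = (mean1 - mean2) / s_pooled with the pooled SD
#' sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2)), which reduces to
#' sqrt((sd1^2 + sd2^2)/2) for equal group sizes.
#'
#' @inheritParams welch_t
#' @return scalar d.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled <= 0) .stopf("zero pooled SD: Cohen's d undefined")
  (mean1 - mean2) / pooled
}

#' Pearson chi-squared test on a 2x2 proportion table with Cramer's V
#'
#' @param successes1,n1 count of responders and group size, group 1.
#' @param successes2,n2 same for group 2.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return A `stat_result` with `statistic` (chi-squared, df = 1), `p`, and
#'   `effect_size` = Cramer's V = sqrt(chi2 / N).
#' @export
chi_square_2x2 <- function(successes1, n1, successes2, n2, correct = FALSE) {
  counts <- c(successes1, n1 - successes1, successes2, n2 - successes2)
  if (any(counts < 0) || n1 <= 0 || n2 <= 0) .stopf("invalid 2x2 counts")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    .stopf("empty margin in 2x2 table: chi-squared undefined")
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  stat_result(statistic = chi2, df = 1,
              p = stats::pchisq(chi2, 1, lower.tail = FALSE),
              effect_size = sqrt(chi2 / n),
              method = "Pearson chi-squared (2x2), Cramer's V")
}

#' Two-way analysis of variance with effect sizes
#'
#' Fits a two-factor ANOVA (both factors crossed) and reports F, degrees of
#' freedom, p, partial eta squared SS_e/(SS_e + SS_err) and generalized eta
#' squared SS_e/(SS_e + sum of all error SS) for each effect. `design =
#' "mixed"` treats `factor_a` as within-subject (requiring `subject`) and uses
#' subject-stratified error terms via `aov` + `Error()`.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factors (coerced); in the mixed design `factor_a`
#'   is the within-subject factor.
#' @param design `"between"` (default) or `"mixed"`.
#' @param subject subject identifier, required for `design = "mixed"`.
#' @param posthoc if `TRUE`, Bonferroni-corrected pairwise t-tests per factor
#'   are attached.
#' @return list with one `stat_result` per effect (`A`, `B`, `A:B`), each
#'   carrying `partial_eta2` and `generalized_eta2`, plus optional `posthoc`.
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          design = c("between", "mixed"), subject = NULL,
                          posthoc = FALSE) {
  design <- match.arg(design)
  a <- factor(factor_a); b <- factor(factor_b)
  if (nlevels(a) < 2 || nlevels(b) < 2) .stopf("each factor needs >= 2 levels")
  dat <- data.frame(y = values, A = a, B = b)
  if (design == "between") {
    fit <- stats::aov(y ~ A * B, data = dat)
    ss <- summary(fit)[[1]]
    rn <- trimws(rownames(ss))
    err_ss <- ss[rn == "Residuals", "Sum Sq"]
    get_eff <- function(term) {
      i <- match(term, rn)
      if (is.na(i)) return(NULL)
      sse <- ss[i, "Sum Sq"]
      res <- stat_result(statistic = ss[i, "F value"],
                         df = c(ss[i, "Df"], ss[rn == "Residuals", "Df"]),
                         p = ss[i, "Pr(>F)"],
                         effect_size = sse / (sse + err_ss),
                         method = "two-way ANOVA (between)")
      res$partial_eta2 <- sse / (sse + err_ss)
      res$generalized_eta2 <- sse / (sse + err_ss)
      res
    }
    out <- list(A = get_eff("A"), B = get_eff("B"), `A:B` = get_eff("A:B"))
  } else {
    if (is.null(subject)) .stopf("mixed design requires 'subject'")
    dat$S <- factor(subject)
    fit <- stats::aov(y ~ A * B + Error(S / A), data = dat)
    sm <- summary(fit)
    tabs <- lapply(sm, function(s) s[[1]])
    all_err <- sum(vapply(tabs, function(tb) {
      rn <- trimws(rownames(tb)); sum(tb[rn == "Residuals", "Sum Sq"])
    }, numeric(1)))
    get_eff <- function(term) {
      for (tb in tabs) {
        rn <- trimws(rownames(tb))
        i <- match(term, rn)
        if (!is.na(i)) {
          sse <- tb[i, "Sum Sq"]
          err_ss <- tb[rn == "Residuals", "Sum Sq"]
          res <- stat_result(statistic = tb[i, "F value"],
                             df = c(tb[i, "Df"], tb[rn == "Residuals", "Df"]),
                             p = tb[i, "Pr(>F)"],
                             effect_size = sse / (sse + err_ss),
                             method = "two-way ANOVA (mixed)")
          res$partial_eta2 <- sse / (sse + err_ss)
          res$generalized_eta2 <- sse / (sse + all_err)
          return(res)
        }
      }
      NULL
    }
    out <- list(A = get_eff("A"), B = get_eff("B"), `A:B` = get_eff("A:B"))
  }
  if (posthoc) {
    out$posthoc <- list(
      A = stats::pairwise.t.test(values, a, p.adjust.method = "bonferroni"),
      B = stats::pairwise.t.test(values, b, p.adjust.method = "bonferroni"))
  }
  out
}

#' Fisher's Z (atanh) transform of a correlation
#'
#' @param r correlation value(s), each with |r| < 1.
#' @return atanh(r).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    .stopf("fisher_z requires |r| < 1")
  atanh(r)
}

#' Spearman rank correlation with Bonferroni correction
#'
#' rho is the Pearson correlation of average ranks (ties averaged). The raw
#' two-sided p is multiplied by the comparison family size and capped at 1.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param family number of tests in the Bonferroni family (default 1).
#' @return `stat_result` with `statistic` = rho, `p` raw, `p_corrected`.
#'   Constant input yields `NA` statistics with a warning.
#' @export
spearman_bonferroni <- function(x, y, family = 1) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) .stopf("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman's rho undefined", call. = FALSE)
    res <- stat_result(statistic = NA_real_, df = n - 2, p = NA_real_,
                       effect_size = NA_real_, method = "Spearman rho")
    res$p_corrected <- NA_real_
    return(res)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  res <- stat_result(statistic = unname(ct$estimate), df = n - 2,
                     p = ct$p.value, effect_size = unname(ct$estimate),
                     method = "Spearman rho (Bonferroni family)")
  res$p_corrected <- min(1, ct$p.value * family)
  res
}

#' Framewise displacement from rigid-body motion parameters
#'
#' FD_t = sum of absolute frame-to-frame translation increments (mm) plus
#' `head_radius` times the absolute rotation increments (radians converted to
#' arc length on a sphere of that radius). The first volume has FD = 0 and is
#' included in the mean.
#'
#' @param motion numeric matrix, volumes x 6: three translations (mm) then
#'   three rotations (radians), or a `motion_trace`.
#' @param head_radius sphere radius in mm (default 50).
#' @return list with `fd` (per-volume vector) and `mean_fd`.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  m <- as.matrix(motion)
  if (ncol(m) != 6) .stopf("motion must have 6 columns (3 trans + 3 rot)")
  if (nrow(m) < 2) .stopf("need >= 2 volumes")
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd))
}

#' One-sample t-test
#'
#' @param values numeric vector, n >= 2, nonzero variance.
#' @param mu0 null-hypothesis mean.
#' @return `stat_result` with t, df, two-sided p and Cohen's d =
#'   (mean - mu0)/sd.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) .stopf("need >= 2 values")
  s <- stats::sd(values)
  if (s == 0) .stopf("zero variance: t undefined")
  t_val <- (mean(values) - mu0) / (s / sqrt(n))
  stat_result(statistic = t_val, df = n - 1,
              p = 2 * stats::pt(abs(t_val), n - 1, lower.tail = FALSE),
              effect_size = (mean(values) - mu0) / s,
              method = "one-sample t")
}

#' Construct a statistic result record
#'
#' @param statistic test statistic value.
#' @param df degrees of freedom (possibly fractional or a length-2 vector).
#' @param p p-value.
#' @param effect_size effect size on the statistic's conventional scale.
#' @param method short description.
#' @return object of class `stat_result`.
#' @export
stat_result <- function(statistic, df, p, effect_size = NA_real_,
                        method = "") {
  structure(list(statistic = statistic, df = df, p = p,
                 effect_size = effect_size, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g, effect size = %.4g\n",
              x$method, x$statistic,
              paste(signif(x$df, 5), collapse = ", "), x$p, x$effect_size))
  invisible(x)
}
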