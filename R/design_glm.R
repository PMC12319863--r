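#' Build the block design of one scanning run
#'
#' One run contains 20 task blocks (10 conditions x 2 repetitions), each 12 s,
#' with fixation-only baseline periods of 27 s before the first block, 12 s
#' after the 5th, 10th and 15th blocks, and 15 s after the 20th block, for a
#' total of 318 s (106 volumes at TR = 3 s).
#'
#' @param condition_order character vector of 20 block labels: a permutation
#'   of each of the 10 conditions twice. Defaults to the fixed pseudo-random
#'   order returned by [default_block_order()].
#' @param TR repetition time in seconds (default 3).
#' @param block_length block duration in seconds (default 12).
#' @return A `run_design` list: `TR`, `block_length`, `blocks` (data.frame of
#'   condition + onset), `baselines` (data.frame of onset + duration),
#'   `total_duration`, `n_volumes`.
#' @export
build_run_design <- function(condition_order = default_block_order(),
                             TR = 3, block_length = 12) {
  .check_scalar(TR, "TR", nonneg = TRUE)
  conds <- bodygeom_conditions()
  if (length(condition_order) != 20 ||
      !identical(sort(condition_order), sort(rep(conds, 2))))
    .stopf("condition_order must contain each of the 10 conditions exactly twice")
  onsets <- numeric(20)
  t <- 27                                  # initial fixation baseline
  baselines <- data.frame(onset = 0, duration = 27)
  for (i in 1:20) {
    onsets[i] <- t
    t <- t + block_length
    if (i %in% c(5, 10, 15)) {
      baselines <- rbind(baselines, data.frame(onset = t, duration = 12))
      t <- t + 12
    }
  }
  baselines <- rbind(baselines, data.frame(onset = t, duration = 15))
  total <- t + 15
  if (abs(total / TR - round(total / TR)) > 1e-9)
    .stopf("total duration %.1f s is not a whole number of TR = %g s volumes",
           total, TR)
  structure(list(TR = TR, block_length = block_length,
                 blocks = data.frame(condition = condition_order,
                                     onset = onsets,
                                     stringsAsFactors = FALSE),
                 baselines = baselines,
                 total_duration = total,
                 n_volumes = as.integer(round(total / TR))),
            class = "run_design")
}

#' @rdname build_run_design
#' @param run run number, used only to vary the fixed pseudo-random block
#'   order between runs deterministically.
#' @export
default_block_order <- function(run = 1) {
  conds <- bodygeom_conditions()
  # fixed latin-square-like rotation: deterministic, every condition twice,
  # no immediate repetition of the same condition
  first <- conds[((seq_len(10) - 1 + (run - 1) * 3) %% 10) + 1]
  second <- conds[((seq_len(10) - 1 + (run - 1) * 3 + 5) %% 10) + 1]
  c(first, second)
}

#' Canonical double-gamma haemodynamic response function
#'
#' The kernel is the difference of two gamma densities (response minus
#' undershoot scaled by `ratio`), sampled on a regular grid and scaled to a
#' peak of 1. With the default parameters (delays 6/16 s, dispersions 1/1,
#' ratio 6) the peak occurs near 5 s.
#'
#' @param response_delay,undershoot_delay gamma means in seconds.
#' @param response_dispersion,undershoot_dispersion gamma scale parameters.
#' @param ratio response-to-undershoot amplitude ratio.
#' @param length kernel length in seconds.
#' @param dt sampling interval in seconds.
#' @return An `hrf_kernel`: list with `t` (times) and `values`
#'   (`length/dt + 1` samples).
#' @export
canonical_hrf <- function(response_delay = 6, undershoot_delay = 16,
                          response_dispersion = 1, undershoot_dispersion = 1,
                          ratio = 6, length = 32, dt = 0.1) {
  if (response_dispersion <= 0 || undershoot_dispersion <= 0)
    .stopf("dispersions must be > 0")
  if (length <= response_delay)
    .stopf("kernel length must exceed the response delay")
  t <- seq(0, length, by = dt)
  values <- stats::dgamma(t, shape = response_delay / response_dispersion,
                          scale = response_dispersion) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_dispersion,
                  scale = undershoot_dispersion) / ratio
  values <- values / max(values)
  structure(list(t = t, values = values, dt = dt), class = "hrf_kernel")
}

# discrete-cosine high-pass basis, K = floor(2 * T / cutoff) regressors
.dct_basis <- function(n_volumes, TR, cutoff) {
  K <- floor(2 * n_volumes * TR / cutoff)
  if (K < 1) return(NULL)
  v <- seq_len(n_volumes) - 1
  b <- vapply(seq_len(K), function(k)
    sqrt(2 / n_volumes) * cos(pi * (2 * v + 1) * k / (2 * n_volumes)),
    numeric(n_volumes))
  colnames(b) <- paste0("dct", seq_len(K))
  b
}

#' Build a first-level design matrix
#'
#' Condition boxcars are built on a fine microtime grid, convolved with the
#' canonical HRF, and sampled at volume acquisition times. A discrete-cosine
#' high-pass basis (cutoff 128 s by default) and optional motion regressors
#' are appended; the constant column is last.
#'
#' @param design a `run_design` from [build_run_design()].
#' @param hrf an `hrf_kernel` (default [canonical_hrf()]).
#' @param motion optional volumes x 6 motion-parameter matrix.
#' @param highpass_cutoff high-pass period in seconds (default 128); must
#'   exceed 2 x TR. `Inf` disables the basis.
#' @return numeric matrix `n_volumes` x regressors with column names; the 10
#'   condition columns come first, attribute `condition_columns` indexes them.
#' @export
build_design_matrix <- function(design, hrf = canonical_hrf(), motion = NULL,
                                highpass_cutoff = 128) {
  stopifnot(inherits(design, "run_design"))
  if (is.finite(highpass_cutoff) && highpass_cutoff <= 2 * design$TR)
    .stopf("highpass cutoff must exceed 2 x TR")
  conds <- bodygeom_conditions()
  dt <- hrf$dt
  n_fine <- round(design$total_duration / dt)
  t_fine <- (seq_len(n_fine) - 1) * dt
  vol_idx <- round(((seq_len(design$n_volumes) - 1) * design$TR) / dt) + 1
  X <- matrix(0, design$n_volumes, length(conds),
              dimnames = list(NULL, conds))
  for (cond in conds) {
    box <- numeric(n_fine)
    ons <- design$blocks$onset[design$blocks$condition == cond]
    for (o in ons)
      box[t_fine >= o & t_fine < o + design$block_length] <- 1
    if (!any(box > 0)) next
    reg <- stats::convolve(box, rev(hrf$values), type = "open")[seq_len(n_fine)]
    X[, cond] <- reg[vol_idx]
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != design$n_volumes)
      .stopf("motion trace length (%d) != n_volumes (%d)",
             nrow(motion), design$n_volumes)
    colnames(motion) <- paste0("motion", 1:6)
    X <- cbind(X, motion)
  }
  if (is.finite(highpass_cutoff)) {
    dct <- .dct_basis(design$n_volumes, design$TR, highpass_cutoff)
    if (!is.null(dct)) X <- cbind(X, dct)
  }
  X <- cbind(X, constant = 1)
  attr(X, "condition_columns") <- seq_along(conds)
  X
}

#' Fit a first-level general linear model
#'
#' Ordinary least squares per voxel. With `whiten = TRUE`, a single AR(1)
#' coefficient is estimated from residuals pooled over voxels and the model is
#' refitted on AR(1)-prewhitened data (an approximation to pooled
#' restricted-ML serial-correlation estimation).
#'
#' @param Y numeric matrix volumes x voxels.
#' @param X design matrix from [build_design_matrix()].
#' @param whiten estimate and remove AR(1) serial correlation.
#' @return A `glm_fit` list: `beta` (regressor x voxel), `residual_variance`,
#'   `df`, `ar1` (estimate or `NA`), `rank_deficient` flag.
#' @export
fit_glm <- function(Y, X, whiten = FALSE) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) .stopf("Y and X row counts differ")
  ols <- function(Xm, Ym) {
    qx <- qr(Xm)
    if (qx$rank < ncol(Xm))
      warning("rank-deficient design: using pivoted least squares; ",
              "contrasts on aliased columns are unreliable", call. = FALSE)
    b <- qr.coef(qx, Ym)
    b[is.na(b)] <- 0
    list(beta = b, resid = Ym - Xm %*% b, rank = qx$rank)
  }
  fit <- ols(X, Y)
  ar1 <- NA_real_
  if (whiten) {
    r <- fit$resid
    num <- sum(r[-1, , drop = FALSE] * r[-nrow(r), , drop = FALSE])
    den <- sum(r^2)
    ar1 <- if (den > 0) num / den else 0
    W <- function(M) rbind(M[1, , drop = FALSE] * sqrt(1 - ar1^2),
                           M[-1, , drop = FALSE] -
                             ar1 * M[-nrow(M), , drop = FALSE])
    fit <- ols(W(X), W(Y))
  }
  df <- nrow(Y) - fit$rank
  rv <- colSums(fit$resid^2) / max(df, 1)
  structure(list(beta = fit$beta, residual_variance = rv, df = df,
                 ar1 = ar1, rank_deficient = fit$rank < ncol(X)),
            class = "glm_fit")
}

#' Contrast estimate from a GLM fit
#'
#' @param fit a `glm_fit`.
#' @param weights named or positional contrast weight vector over regressors
#'   (unnamed regressors get weight 0 when `weights` is named).
#' @return numeric vector, one contrast value per voxel.
#' @export
contrast_estimate <- function(fit, weights) {
  b <- fit$beta
  w <- numeric(nrow(b))
  if (!is.null(names(weights))) {
    idx <- match(names(weights), rownames(b))
    if (anyNA(idx)) .stopf("unknown regressor in contrast: %s",
                           paste(names(weights)[is.na(idx)], collapse = ", "))
    w[idx] <- weights
  } else {
    if (length(weights) != nrow(b)) .stopf("contrast length mismatch")
    w <- weights
  }
  drop(crossprod(w, b))
}

#' Voxel-wise group t-map
#'
#' @param contrasts subjects x voxels matrix of contrast values (one-sample
#'   mode) or group 1 matrix (two-sample mode).
#' @param contrasts2 group 2 matrix for `mode = "two-sample"` (Welch).
#' @param mode `"one-sample"` or `"two-sample"`.
#' @param alpha uncorrected threshold probability for the mask (default 0.01).
#' @return list: `t` (per voxel), `df`, `p`, `mask` (p < alpha); zero-variance
#'   voxels get `NA` and are excluded from the mask with a warning.
#' @export
group_t_map <- function(contrasts, contrasts2 = NULL,
                        mode = c("one-sample", "two-sample"), alpha = 0.01) {
  mode <- match.arg(mode)
  C1 <- as.matrix(contrasts)
  if (nrow(C1) < 2) .stopf("need >= 2 subjects")
  if (mode == "one-sample") {
    n <- nrow(C1)
    m <- colMeans(C1)
    s <- apply(C1, 2, stats::sd)
    tv <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
    df <- rep(n - 1, ncol(C1))
  } else {
    if (is.null(contrasts2)) .stopf("two-sample mode needs contrasts2")
    C2 <- as.matrix(contrasts2)
    v1 <- apply(C1, 2, stats::var) / nrow(C1)
    v2 <- apply(C2, 2, stats::var) / nrow(C2)
    tv <- ifelse(v1 + v2 > 0,
                 (colMeans(C1) - colMeans(C2)) / sqrt(v1 + v2), NA_real_)
    df <- ifelse(v1 + v2 > 0,
                 (v1 + v2)^2 / (v1^2 / (nrow(C1) - 1) + v2^2 / (nrow(C2) - 1)),
                 NA_real_)
  }
  if (anyNA(tv))
    warning("zero-variance voxels masked out of the t-map", call. = FALSE)
  p <- stats::pt(tv, df, lower.tail = FALSE)
  list(t = tv, df = df, p = p, mask = !is.na(p) & p < alpha, alpha = alpha)
}
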