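#' Configuration for a synthetic cohort
#'
#' Describes the generative model for synthetic subjects: run-wise voxel
#' patterns with a three-category cluster structure over the 8 body-part
#' conditions (action effectors hand/foot/arm/leg; faces upper/lower face;
#' non-effectors chest/waist), plus whole-body and chair conditions for the
#' univariate localizer contrast.
#'
#' @param n_per_group subjects per group (TD-like and ASD-like).
#' @param n_voxels voxels per subject ROI (>= 2).
#' @param n_runs number of runs (even, >= 2; default 4).
#' @param category_separation distance scale between category mean patterns.
#' @param condition_separation spread of condition patterns around their
#'   category mean.
#' @param run_noise_sd SD of i.i.d. run-level noise added to each beta.
#' @param group_shift mean pattern offset of ASD-like minus TD-like subjects
#'   (default 0: identical generative geometry in both groups).
#' @param localizer_amplitude uniform activation added to the whole-body
#'   condition and subtracted from the chair condition, so the whole-body vs
#'   chair contrast localizes the ROI.
#' @param seed master integer seed; every generated quantity is a pure
#'   function of (config, seed, subject index).
#' @return A validated `cohort_config` list. `n_conditions` is fixed at 10 in
#'   the documented order of [bodygeom_conditions()].
#' @export
cohort_config <- function(n_per_group, n_voxels, n_runs = 4,
                          category_separation = 1, condition_separation = 0.5,
                          run_noise_sd = 0.5, group_shift = 0,
                          localizer_amplitude = 1, seed = 1) {
  .check_scalar(n_per_group, "n_per_group", nonneg = TRUE, integer = TRUE)
  .check_scalar(n_voxels, "n_voxels", nonneg = TRUE, integer = TRUE)
  .check_scalar(n_runs, "n_runs", nonneg = TRUE, integer = TRUE)
  .check_scalar(category_separation, "category_separation", nonneg = TRUE)
  .check_scalar(condition_separation, "condition_separation", nonneg = TRUE)
  .check_scalar(run_noise_sd, "run_noise_sd", nonneg = TRUE)
  .check_scalar(group_shift, "group_shift")
  .check_scalar(seed, "seed", integer = TRUE)
  if (n_voxels < 2) .stopf("n_voxels must be >= 2 (correlations need >= 2 voxels)")
  if (n_runs < 2 || n_runs %% 2 != 0)
    .stopf("n_runs must be even and >= 2 (odd/even split-half)")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_voxels = as.integer(n_voxels),
                 n_runs = as.integer(n_runs),
                 n_conditions = 10L,
                 category_separation = category_separation,
                 condition_separation = condition_separation,
                 run_noise_sd = run_noise_sd,
                 group_shift = group_shift,
                 localizer_amplitude = localizer_amplitude,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate one subject's run-wise condition x voxel beta patterns
#'
#' Per subject, each of the three body-part categories (plus whole body and
#' chair) receives a mean voxel pattern drawn standard-normal and scaled by
#' `category_separation`; each condition adds an offset pattern scaled by
#' `condition_separation`; each run adds i.i.d. Gaussian noise of SD
#' `run_noise_sd`. ASD-like subjects additionally receive `group_shift` on
#' every beta. The chair mean pattern is the negative of the whole-body mean
#' (maximally distant), and the localizer amplitude is added/subtracted
#' uniformly so the whole-body vs chair contrast is positive in the ROI.
#'
#' Subjects `1..n_per_group` are TD-like; `n_per_group+1 .. 2*n_per_group`
#' are ASD-like.
#'
#' @param config a [cohort_config()].
#' @param subject_index subject number in `1..2*n_per_group`.
#' @return A `voxel_pattern_set`: list with `subject`, `group`, and `betas`,
#'   an array `[run, condition, voxel]` with condition dimnames in the fixed
#'   order of [bodygeom_conditions()].
#' @export
generate_pattern_set <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"))
  .check_scalar(subject_index, "subject_index", nonneg = TRUE, integer = TRUE)
  if (subject_index < 1 || subject_index > 2 * config$n_per_group)
    .stopf("subject_index out of range 1..%d", 2 * config$n_per_group)
  group <- if (subject_index <= config$n_per_group) "TD-like" else "ASD-like"
  conds <- bodygeom_conditions()
  set.seed(.subject_seed(config$seed, subject_index))
  nv <- config$n_voxels
  cat_means <- list(
    effector = config$category_separation * stats::rnorm(nv),
    face = config$category_separation * stats::rnorm(nv),
    `non-effector` = config$category_separation * stats::rnorm(nv),
    `whole body` = config$category_separation * stats::rnorm(nv))
  cat_means[["chair"]] <- -cat_means[["whole body"]]
  cat_of <- c(`whole body` = "whole body", chair = "chair",
              hypothesized_partition())
  cond_means <- matrix(0, length(conds), nv, dimnames = list(conds, NULL))
  for (cond in conds)
    cond_means[cond, ] <- cat_means[[cat_of[[cond]]]] +
      config$condition_separation * stats::rnorm(nv)
  cond_means["whole body", ] <- cond_means["whole body", ] +
    config$localizer_amplitude
  cond_means["chair", ] <- cond_means["chair", ] - config$localizer_amplitude
  betas <- array(0, dim = c(config$n_runs, length(conds), nv),
                 dimnames = list(NULL, conds, NULL))
  shift <- if (group == "ASD-like") config$group_shift else 0
  for (r in seq_len(config$n_runs))
    betas[r, , ] <- cond_means + shift +
      config$run_noise_sd * matrix(stats::rnorm(length(conds) * nv),
                                   length(conds), nv)
  structure(list(subject = subject_index, group = group, betas = betas),
            class = "voxel_pattern_set")
}

#' Generate all subjects of a cohort
#'
#' @inheritParams generate_pattern_set
#' @return list of `voxel_pattern_set`, length `2 * n_per_group`.
#' @export
generate_cohort <- function(config) {
  lapply(seq_len(2 * config$n_per_group),
         function(i) generate_pattern_set(config, i))
}

# group means/SDs per trait: TD-like then ASD-like (demographic-table scale)
.TRAIT_PARAMS <- list(
  age = c(31.0, 10.2, 30.4, 5.3),
  fsiq = c(111.0, 14.4, 109.0, 12.0),
  srs_total = c(54.9, 21.2, 106.0, 28.9),
  aq_total = c(16.0, 7.0, 33.0, 5.0),
  sp_low_registration = c(27.4, 7.5, 33.7, 8.7),
  sp_sensory_seeking = c(38.1, 6.4, 30.7, 6.6),
  sp_sensory_sensitivity = c(33.9, 6.9, 40.2, 9.7),
  sp_sensation_avoiding = c(34.7, 6.3, 40.9, 11.4))

#' Generate a trait table for a synthetic cohort
#'
#' Scores (age, FSIQ, SRS total, AQ total, and four sensory-profile
#' sub-scales) are drawn from group-specific normal distributions whose
#' default means and SDs follow the demographic profile the generator
#' emulates (e.g. AQ total 16.0 +/- 7.0 TD-like, 33.0 +/- 5.0 ASD-like).
#' Traits are independent of the neural patterns unless `coupling` is nonzero,
#' in which case each trait is a mixture `(1-coupling)*noise +
#' coupling*scale(neural_scores)` on the same mean/SD scale, creating
#' recoverable brain-trait correlations for testing.
#'
#' @param config a [cohort_config()].
#' @param coupling mixing weight in `[0, 1]` toward `neural_scores`.
#' @param neural_scores optional per-subject scores (length `2*n_per_group`)
#'   to couple traits to.
#' @return data.frame, one row per subject: `subject`, `group`, 8 trait
#'   columns.
#' @export
generate_traits <- function(config, coupling = 0, neural_scores = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_per_group
  group <- rep(c("TD-like", "ASD-like"), each = n)
  set.seed(.subject_seed(config$seed, 0L, salt = 1L))
  out <- data.frame(subject = seq_len(2 * n), group = group,
                    stringsAsFactors = FALSE)
  z_mix <- if (coupling > 0) {
    if (is.null(neural_scores) || length(neural_scores) != 2 * n)
      .stopf("coupling > 0 requires neural_scores of length %d", 2 * n)
    as.numeric(scale(neural_scores))
  } else numeric(2 * n)
  for (trait in names(.TRAIT_PARAMS)) {
    p <- .TRAIT_PARAMS[[trait]]
    mu <- ifelse(group == "TD-like", p[1], p[3])
    sd <- ifelse(group == "TD-like", p[2], p[4])
    z <- (1 - coupling) * stats::rnorm(2 * n) + coupling * z_mix
    out[[trait]] <- mu + sd * z
  }
  out
}

#' Generate voxel time series from beta patterns (forward model)
#'
#' Each run's series is the design-matrix prediction `X_cond %*% t(betas)`
#' using the same convolved condition regressors the GLM uses, plus a
#' low-frequency cosine drift and AR(1) noise. This is the forward model the
#' first-level GLM inverts; with zero noise and drift, [fit_glm()] recovers
#' the betas exactly.
#'
#' @param patterns a `voxel_pattern_set`.
#' @param design a `run_design` (or list of one per run).
#' @param ar_coefficient AR(1) coefficient of the noise process.
#' @param drift_amplitude amplitude of a half-period cosine drift.
#' @param noise_sd marginal SD of the AR(1) noise (innovation SD is scaled so
#'   the stationary SD equals `noise_sd`).
#' @param seed integer seed.
#' @param hrf HRF kernel used for the condition regressors.
#' @return list of run matrices (volumes x voxels), with the per-run design
#'   matrices attached as attribute `design_matrices`.
#' @export
generate_timeseries <- function(patterns, design, ar_coefficient = 0,
                                drift_amplitude = 0, noise_sd = 0, seed = 1,
                                hrf = canonical_hrf()) {
  stopifnot(inherits(patterns, "voxel_pattern_set"))
  n_runs <- dim(patterns$betas)[1]
  designs <- if (inherits(design, "run_design"))
    rep(list(design), n_runs) else design
  if (length(designs) != n_runs) .stopf("need one design per run")
  conds_p <- dimnames(patterns$betas)[[2]]
  if (!all(conds_p %in% bodygeom_conditions()))
    .stopf("pattern conditions do not match the design's condition set")
  if (abs(ar_coefficient) >= 1) .stopf("|ar_coefficient| must be < 1")
  set.seed(.subject_seed(seed, patterns$subject, salt = 2L))
  out <- vector("list", n_runs)
  Xs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    d <- designs[[r]]
    X <- build_design_matrix(d, hrf = hrf, highpass_cutoff = Inf)
    Xc <- X[, conds_p, drop = FALSE]
    B <- patterns$betas[r, , ]                    # condition x voxel
    Y <- Xc %*% B
    nvol <- d$n_volumes
    if (drift_amplitude != 0) {
      drift <- drift_amplitude *
        cos(pi * (seq_len(nvol) - 1) / (nvol - 1))
      Y <- Y + drift
    }
    if (noise_sd > 0) {
      innov_sd <- noise_sd * sqrt(1 - ar_coefficient^2)
      E <- apply(matrix(stats::rnorm(nvol * ncol(Y), sd = innov_sd),
                        nvol, ncol(Y)), 2,
                 function(e) as.numeric(
                   stats::filter(e, ar_coefficient, method = "recursive")))
      Y <- Y + E
    }
    out[[r]] <- Y
    Xs[[r]] <- X
  }
  attr(out, "design_matrices") <- Xs
  out
}

#' Generate random-walk head-motion parameters
#'
#' Three translations (mm) and three rotations (radians) evolve as Gaussian
#' random walks with per-step SD `amplitude` for translations and
#' `amplitude / 50` for rotations (so a 50 mm head radius converts both to
#' comparable millimetre displacement).
#'
#' @param n_volumes number of volumes (>= 1).
#' @param amplitude random-walk step SD in mm; 0 gives constant traces.
#' @param seed integer seed.
#' @return A `motion_trace`: numeric matrix `n_volumes` x 6 with columns
#'   `trans_x/y/z`, `rot_x/y/z`.
#' @export
generate_motion_params <- function(n_volumes, amplitude = 0.05, seed = 1) {
  .check_scalar(n_volumes, "n_volumes", nonneg = TRUE, integer = TRUE)
  if (n_volumes < 1) .stopf("n_volumes must be >= 1")
  set.seed(as.integer(seed))
  steps <- matrix(stats::rnorm(n_volumes * 6), n_volumes, 6)
  steps[1, ] <- 0
  steps[, 1:3] <- steps[, 1:3] * amplitude
  steps[, 4:6] <- steps[, 4:6] * amplitude / 50
  m <- apply(steps, 2, cumsum)
  m <- matrix(m, nrow = n_volumes)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  structure(m, class = c("motion_trace", "matrix", "array"))
}

#' Write a synthetic cohort to disk as plain text
#'
#' Betas go to one long CSV (`subject, group, run, condition, voxel, beta`),
#' traits to `traits.csv`, and a JSON manifest records the configuration.
#' When `grid_dim` is supplied and the RNifti package is available, each
#' run x condition beta pattern is additionally written as a 3D NIfTI volume.
#'
#' @param cohort list of `voxel_pattern_set` (from [generate_cohort()]).
#' @param traits data.frame from [generate_traits()].
#' @param dir output directory (created if needed).
#' @param config the generating [cohort_config()], stored in the manifest.
#' @param grid_dim optional length-3 integer vector to reshape voxels into a
#'   3D grid for NIfTI export.
#' @return invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, traits, dir, config = NULL, grid_dim = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(cohort, function(ps) {
    b <- ps$betas
    dn <- dimnames(b)[[2]]
    data.frame(subject = ps$subject, group = ps$group,
               run = rep(seq_len(dim(b)[1]), times = dim(b)[2] * dim(b)[3]),
               condition = rep(rep(dn, each = dim(b)[1]), times = dim(b)[3]),
               voxel = rep(seq_len(dim(b)[3]), each = dim(b)[1] * dim(b)[2]),
               beta = as.vector(b), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, file.path(dir, "betas.csv"), row.names = FALSE)
  utils::write.csv(traits, file.path(dir, "traits.csv"), row.names = FALSE)
  manifest <- list(n_subjects = length(cohort),
                   conditions = bodygeom_conditions(),
                   config = if (!is.null(config)) unclass(config),
                   files = c("betas.csv", "traits.csv"))
  if (!is.null(grid_dim)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      .stopf("NIfTI export requires the RNifti package")
    if (prod(grid_dim) != dim(cohort[[1]]$betas)[3])
      .stopf("grid_dim does not match the voxel count")
    for (ps in cohort) {
      b <- ps$betas
      for (r in seq_len(dim(b)[1])) for (ci in seq_len(dim(b)[2])) {
        vol <- array(b[r, ci, ], dim = grid_dim)
        f <- file.path(dir, sprintf("sub-%02d_run-%d_cond-%02d.nii.gz",
                                    ps$subject, r, ci))
        RNifti::writeNifti(vol, f)
      }
    }
    manifest$nifti <- TRUE
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `betas.csv` and `traits.csv`.
#' @return list with `cohort` (list of `voxel_pattern_set`) and `traits`.
#' @export
read_cohort <- function(dir) {
  rows <- utils::read.csv(file.path(dir, "betas.csv"),
                          stringsAsFactors = FALSE)
  traits <- utils::read.csv(file.path(dir, "traits.csv"),
                            stringsAsFactors = FALSE)
  conds <- bodygeom_conditions()
  cohort <- lapply(split(rows, rows$subject), function(d) {
    n_runs <- max(d$run); n_vox <- max(d$voxel)
    b <- array(NA_real_, dim = c(n_runs, length(conds), n_vox),
               dimnames = list(NULL, conds, NULL))
    b[cbind(d$run, match(d$condition, conds), d$voxel)] <- d$beta
    structure(list(subject = d$subject[1], group = d$group[1], betas = b),
              class = "voxel_pattern_set")
  })
  cohort <- cohort[order(vapply(cohort, `[[`, numeric(1), "subject"))]
  list(cohort = unname(cohort), traits = traits)
}
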