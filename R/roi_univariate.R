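#' Sphere ROI specification
#'
#' @param center length-3 MNI millimetre coordinate of the sphere center.
#' @param diameter sphere diameter in mm (default 8).
#' @param voxel_size isotropic voxel size in mm (default 2).
#' @param origin millimetre coordinate of voxel `[1, 1, 1]`'s center
#'   (default `c(0, 0, 0)`).
#' @return An `roi_spec` list.
#' @export
roi_spec <- function(center, diameter = 8, voxel_size = 2,
                     origin = c(0, 0, 0)) {
  if (length(center) != 3 || any(!is.finite(center)))
    .stopf("center must be a finite length-3 coordinate")
  .check_scalar(diameter, "diameter", nonneg = TRUE)
  .check_scalar(voxel_size, "voxel_size", nonneg = TRUE)
  if (voxel_size <= 0) .stopf("voxel_size must be > 0")
  structure(list(center = as.numeric(center), diameter = diameter,
                 voxel_size = voxel_size, origin = as.numeric(origin)),
            class = "roi_spec")
}

#' Voxels inside a sphere ROI
#'
#' Returns every voxel whose center lies within `diameter / 2` of the sphere
#' center (inclusive). Inclusion is decided on voxel centers; edge handling is
#' by this center-within-radius rule. An 8 mm diameter sphere on a 2 mm grid
#' centered on a voxel center contains 33 voxels.
#'
#' @param spec an [roi_spec()].
#' @param grid_dim optional length-3 grid dimensions; when supplied, voxels
#'   outside `1..grid_dim` are dropped and linear indices are attached.
#' @return data.frame with integer grid indices `i, j, k`, millimetre centers
#'   `x, y, z`, and (with `grid_dim`) a `linear` index column.
#' @export
sphere_voxels <- function(spec, grid_dim = NULL) {
  stopifnot(inherits(spec, "roi_spec"))
  r <- spec$diameter / 2
  vs <- spec$voxel_size
  # integer grid index range covering the bounding box
  lo <- floor((spec$center - r - spec$origin) / vs) + 1
  hi <- ceiling((spec$center + r - spec$origin) / vs) + 1
  g <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  ctr <- cbind(spec$origin[1] + (g$i - 1) * vs,
               spec$origin[2] + (g$j - 1) * vs,
               spec$origin[3] + (g$k - 1) * vs)
  d2 <- rowSums(sweep(ctr, 2, spec$center)^2)
  keep <- d2 <= r^2 + 1e-9
  out <- data.frame(i = g$i[keep], j = g$j[keep], k = g$k[keep],
                    x = ctr[keep, 1], y = ctr[keep, 2], z = ctr[keep, 3])
  if (!is.null(grid_dim)) {
    inside <- out$i >= 1 & out$i <= grid_dim[1] &
      out$j >= 1 & out$j <= grid_dim[2] &
      out$k >= 1 & out$k <= grid_dim[3]
    out <- out[inside, , drop = FALSE]
    out$linear <- out$i + (out$j - 1) * grid_dim[1] +
      (out$k - 1) * grid_dim[1] * grid_dim[2]
  }
  rownames(out) <- NULL
  out
}

#' Localize an individual's responsive voxels within a sphere ROI
#'
#' Thresholds a voxel-wise t-map at the upper-`alpha` Student-t quantile
#' (uncorrected) inside the sphere. A subject is a responder when at least one
#' sphere voxel exceeds threshold; the peak is the maximum-t voxel; extent is
#' the suprathreshold voxel count, also expressed in mm^3 (count x voxel
#' volume).
#'
#' @param t_map 3D numeric array of t values; its grid geometry is taken from
#'   `spec` (`voxel_size`, `origin`).
#' @param spec an [roi_spec()].
#' @param df degrees of freedom of the t-map.
#' @param alpha uncorrected threshold probability (default 0.01).
#' @return An `roi_result` list: `responder`, `threshold`, `peak_mm`,
#'   `peak_index`, `peak_t`, `extent_voxels`, `extent_mm3`, `voxels` (the
#'   sphere voxel table).
#' @export
localize_individual_roi <- function(t_map, spec, df, alpha = 0.01) {
  stopifnot(inherits(spec, "roi_spec"), is.array(t_map),
            length(dim(t_map)) == 3)
  vox <- sphere_voxels(spec)
  dims <- dim(t_map)
  if (any(vox$i < 1) || any(vox$j < 1) || any(vox$k < 1) ||
      any(vox$i > dims[1]) || any(vox$j > dims[2]) || any(vox$k > dims[3]))
    .stopf("sphere extends outside the t-map grid")
  tv <- t_map[cbind(vox$i, vox$j, vox$k)]
  threshold <- stats::qt(1 - alpha, df)
  supra <- tv > threshold
  peak <- which.max(tv)
  structure(list(
    responder = any(supra),
    threshold = threshold,
    peak_mm = unlist(vox[peak, c("x", "y", "z")]),
    peak_index = unlist(vox[peak, c("i", "j", "k")]),
    peak_t = tv[peak],
    extent_voxels = sum(supra),
    extent_mm3 = sum(supra) * spec$voxel_size^3,
    voxels = vox), class = "roi_result")
}

#' Mean beta per body-part condition over an ROI
#'
#' Averages the parameter estimates over the selected voxels and all runs for
#' each of the 8 body-part conditions (whole body and chair are excluded; in
#' the GLM the betas are already expressed relative to the fixation baseline
#' carried by the constant regressor).
#'
#' @param patterns a `voxel_pattern_set`.
#' @param voxels integer indices into the voxel dimension.
#' @return named numeric vector, one mean beta per body-part condition.
#' @export
extract_condition_means <- function(patterns, voxels) {
  stopifnot(inherits(patterns, "voxel_pattern_set"))
  if (length(voxels) == 0) .stopf("empty voxel set")
  b <- patterns$betas[, body_part_conditions(), voxels, drop = FALSE]
  apply(b, 2, mean)
}
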