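#' Split-half representational dissimilarity matrix
#'
#' Condition patterns are averaged separately over odd runs (1, 3, ...) and
#' even runs (2, 4, ...). For conditions i, j the Pearson correlation across
#' voxels between the odd-half pattern of i and the even-half pattern of j
#' gives r_ij; the dissimilarity matrix is D = 1 - (r_ij + r_ji)/2, which
#' symmetrizes the split-half matrix by averaging the two split directions.
#' The diagonal (1 - r_ii) is stored but excluded from all inference.
#'
#' @param patterns a `voxel_pattern_set`.
#' @param voxels optional integer voxel indices (default: all voxels).
#' @return An `rdm`: 8 x 8 symmetric matrix over the body-part conditions with
#'   entries in `[0, 2]`, carrying `subject` and `group` attributes.
#' @export
compute_split_half_rdm <- function(patterns, voxels = NULL) {
  stopifnot(inherits(patterns, "voxel_pattern_set"))
  b <- patterns$betas
  n_runs <- dim(b)[1]
  if (n_runs < 2) .stopf("need >= 2 runs for a split-half RDM")
  if (is.null(voxels)) voxels <- seq_len(dim(b)[3])
  if (length(voxels) < 2) .stopf("need >= 2 voxels")
  conds <- body_part_conditions()
  odd <- seq(1, n_runs, by = 2)
  even <- seq(2, n_runs, by = 2)
  half_mean <- function(runs) {
    m <- apply(b[runs, conds, voxels, drop = FALSE], c(2, 3), mean)
    matrix(m, nrow = length(conds), dimnames = list(conds, NULL))
  }
  O <- half_mean(odd)
  E <- half_mean(even)
  for (half in c("odd", "even")) {
    H <- if (half == "odd") O else E
    zero <- apply(H, 1, stats::sd) == 0
    if (any(zero))
      .stopf("zero-variance pattern for condition '%s' in the %s half",
             conds[which(zero)[1]], half)
  }
  R <- stats::cor(t(O), t(E))            # r_ij: odd i vs even j
  D <- 1 - (R + t(R)) / 2
  dimnames(D) <- list(conds, conds)
  structure(D, class = c("rdm", "matrix", "array"),
            subject = patterns$subject, group = patterns$group)
}

#' Element-wise mean of dissimilarity matrices
#'
#' @param rdms list of `rdm` matrices with identical condition order.
#' @param leave_out optional index (into `rdms`) of a subject to exclude,
#'   e.g. for leave-one-out group means.
#' @return an `rdm` of the same shape.
#' @export
aggregate_rdms <- function(rdms, leave_out = NULL) {
  if (length(rdms) == 0) .stopf("empty RDM list")
  dn <- dimnames(rdms[[1]])
  for (m in rdms)
    if (!identical(dimnames(m), dn))
      .stopf("inconsistent condition ordering across RDMs")
  if (!is.null(leave_out)) {
    rdms <- rdms[-leave_out]
    if (length(rdms) == 0) .stopf("leave_out removed the only RDM")
  }
  out <- Reduce(`+`, lapply(rdms, unclass)) / length(rdms)
  structure(out, class = c("rdm", "matrix", "array"))
}

#' Off-diagonal vector of a dissimilarity matrix
#'
#' @param D symmetric dissimilarity matrix.
#' @return the lower-triangle values (28 for 8 conditions), column-major.
#' @export
rdm_offdiag <- function(D) unclass(D)[lower.tri(D)]

#' Metric multidimensional scaling by stress majorization
#'
#' Embeds the conditions in `k` dimensions by minimizing raw stress with the
#' SMACOF (Guttman-transform) iteration, starting from the classical-scaling
#' solution plus seed-controlled random restarts, and reports normalized
#' stress-1 = sqrt(sum (d - delta)^2 / sum delta^2). Used for visualization
#' only.
#'
#' @param D dissimilarity matrix.
#' @param k embedding dimension (`0 < k <` number of conditions).
#' @param seed integer seed for the random restarts.
#' @param n_restarts number of random initializations in addition to the
#'   classical-scaling start.
#' @param max_iter,tol iteration controls.
#' @return An `mds_embedding`: list with `points` (conditions x k), `stress`,
#'   and `stress_trace` of the winning run (nonincreasing).
#' @export
mds_embed <- function(D, k = 2, seed = 1, n_restarts = 4, max_iter = 300,
                      tol = 1e-10) {
  n <- nrow(D)
  if (k <= 0) .stopf("k must be positive")
  if (k >= n) .stopf("k must be smaller than the number of conditions")
  delta <- as.matrix(unclass(D))
  diag(delta) <- 0
  denom <- sum(delta^2)
  run_smacof <- function(X) {
    trace <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      d <- as.matrix(stats::dist(X))
      stress <- sqrt(sum((d[lower.tri(d)] - delta[lower.tri(delta)])^2) /
                       (denom / 2))
      trace <- c(trace, stress)
      if (prev - stress < tol) break
      prev <- stress
      # Guttman transform (unit weights)
      ratio <- ifelse(d > 0, delta / d, 0)
      Bm <- -ratio
      diag(Bm) <- 0
      diag(Bm) <- -rowSums(Bm)
      X <- Bm %*% X / n
    }
    list(points = X, stress = trace[length(trace)], stress_trace = trace)
  }
  inits <- list(suppressWarnings(
    stats::cmdscale(delta, k = k, add = TRUE)$points))
  set.seed(as.integer(seed))
  for (i in seq_len(n_restarts))
    inits <- c(inits, list(matrix(stats::rnorm(n * k), n, k)))
  fits <- lapply(inits, run_smacof)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  rownames(best$points) <- rownames(D)
  structure(best, class = "mds_embedding")
}

#' Serialize an RDM to CSV (wide) and TSV (long)
#'
#' @param D an `rdm`.
#' @param file output path; a `.tsv` long-format companion
#'   (`cond_i, cond_j, dissimilarity`) is written next to it.
#' @return invisibly, `file`.
#' @export
write_rdm <- function(D, file) {
  utils::write.csv(as.data.frame(unclass(D)), file)
  long <- data.frame(cond_i = rep(rownames(D), times = ncol(D)),
                     cond_j = rep(colnames(D), each = nrow(D)),
                     dissimilarity = as.vector(unclass(D)))
  utils::write.table(long, sub("\\.csv$", ".tsv", file), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
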