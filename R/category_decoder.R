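#' Build decoding samples from run-wise beta patterns
#'
#' One sample per run x body-part condition (32 for 4 runs x 8 conditions);
#' features are the ROI-restricted beta values; labels follow the supplied
#' category model (16 effector / 8 face / 8 non-effector under the
#' hypothesized partition).
#'
#' @param patterns a `voxel_pattern_set`.
#' @param voxels integer voxel indices (default all).
#' @param model named condition-to-category assignment.
#' @return A `decoding_samples` list: `features` (samples x voxels), `run`,
#'   `condition`, `category`.
#' @export
build_samples <- function(patterns, voxels = NULL,
                          model = hypothesized_partition()) {
  stopifnot(inherits(patterns, "voxel_pattern_set"))
  b <- patterns$betas
  if (is.null(voxels)) voxels <- seq_len(dim(b)[3])
  conds <- body_part_conditions()
  if (!all(conds %in% dimnames(b)[[2]]))
    .stopf("missing body-part conditions in the pattern set")
  if (!all(conds %in% names(model))) .stopf("model must label every condition")
  n_runs <- dim(b)[1]
  feats <- do.call(rbind, lapply(seq_len(n_runs), function(r)
    matrix(b[r, conds, voxels], nrow = length(conds))))
  structure(list(features = feats,
                 run = rep(seq_len(n_runs), each = length(conds)),
                 condition = rep(conds, times = n_runs),
                 category = rep(unname(model[conds]), times = n_runs)),
            class = "decoding_samples")
}

# one LORO fold: bootstrap-balanced linear SVM accuracy on the held-out run
.fold_accuracy <- function(samples, test_run, n_bootstrap, fold_seed,
                           category = samples$category) {
  tr <- samples$run != test_run
  te <- !tr
  y_tr <- factor(category[tr])
  if (nlevels(droplevels(y_tr)) < length(unique(category)))
    .stopf("a class is absent from the training folds")
  X_tr <- samples$features[tr, , drop = FALSE]
  X_te <- samples$features[te, , drop = FALSE]
  y_te <- factor(category[te], levels = levels(y_tr))
  m <- min(table(y_tr))
  by_class <- split(seq_along(y_tr), y_tr)
  set.seed(fold_seed)
  acc <- numeric(n_bootstrap)
  for (bidx in seq_len(n_bootstrap)) {
    keep <- unlist(lapply(by_class, function(ix)
      if (length(ix) > m) sample(ix, m) else ix), use.names = FALSE)
    fit <- e1071::svm(X_tr[keep, , drop = FALSE], droplevels(y_tr[keep]),
                      kernel = "linear", cost = 1, scale = FALSE)
    pred <- stats::predict(fit, X_te)
    acc[bidx] <- mean(as.character(pred) == as.character(y_te))
  }
  mean(acc)
}

#' Decode category with leave-one-run-out cross-validation
#'
#' For each fold one run is held out; within each of `n_bootstrap` draws the
#' majority training classes are subsampled without replacement to the
#' minority class size (6 samples under the hypothesized 4/2/2 partition with
#' 3 training runs), a linear SVM (C = 1, one-vs-one multiclass, no feature
#' scaling) is trained and the held-out run predicted. The reported accuracy
#' averages proportion correct over bootstraps and folds; chance is 1/3.
#'
#' @param samples a `decoding_samples`.
#' @param n_bootstrap bootstrap draws per fold (default 100).
#' @param seed master seed; per-fold sub-seeds are derived from it.
#' @return scalar accuracy in `[0, 1]`.
#' @export
decode_subject <- function(samples, n_bootstrap = 100, seed = 1) {
  runs <- sort(unique(samples$run))
  if (length(runs) < 2) .stopf("need >= 2 runs for cross-validation")
  accs <- vapply(seq_along(runs), function(fi)
    .fold_accuracy(samples, runs[fi], n_bootstrap,
                   .subject_seed(seed, fi, salt = 3L)),
    numeric(1))
  mean(accs)
}

#' Group-level inference on decoding accuracies
#'
#' @param acc1,acc2 per-subject accuracies of the two groups.
#' @param chance chance level (default 1/3).
#' @return list: `group1`, `group2` (one-sample t vs chance with Cohen's d),
#'   `between` (Welch two-sample t with Cohen's d).
#' @export
decoding_group_inference <- function(acc1, acc2, chance = 1 / 3) {
  list(group1 = one_sample_t(acc1, chance),
       group2 = one_sample_t(acc2, chance),
       between = welch_t_data(acc1, acc2))
}

#' Permutation test of decoding accuracy over all category relabelings
#'
#' Re-runs the full leave-one-run-out decoding under every enumerated
#' condition-to-category assignment (420 for sizes 4/2/2); the hypothesized
#' assignment is entry 1 of the null. p = fraction of null accuracies >= the
#' hypothesized accuracy (included), so p >= 1/420.
#'
#' @param samples a `decoding_samples` built with the hypothesized model.
#' @param n_bootstrap bootstrap draws per fold.
#' @param seed master seed (the same bootstrap sub-seeds are reused across
#'   relabelings so models differ only in their labels).
#' @param models optional precomputed partition matrix.
#' @return list: `accuracy` (hypothesized), `null` (420 accuracies), `p`.
#' @export
decoding_permutation_test <- function(samples, n_bootstrap = 100, seed = 1,
                                      models = NULL) {
  conds <- body_part_conditions()
  if (is.null(models)) models <- enumerate_partitions(items = conds)
  runs <- sort(unique(samples$run))
  null <- vapply(seq_len(nrow(models)), function(mi) {
    category <- unname(models[mi, samples$condition])
    mean(vapply(seq_along(runs), function(fi)
      .fold_accuracy(samples, runs[fi], n_bootstrap,
                     .subject_seed(seed, fi, salt = 3L),
                     category = category),
      numeric(1)))
  }, numeric(1))
  list(accuracy = null[1], null = null, p = mean(null >= null[1]))
}
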