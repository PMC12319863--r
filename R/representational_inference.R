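#' Enumerate all labeled category partitions of the conditions
#'
#' All assignments of the conditions to the three labeled categories with the
#' fixed sizes (4 effector, 2 face, 2 non-effector by default): choose 4 of 8
#' for effector, then 2 of the remaining 4 for face, giving
#' C(8,4) x C(4,2) = 420 models. The order is deterministic with the
#' hypothesized model first. Because the ANOSIM statistic depends only on the
#' within/between split, swapping the two size-2 category labels leaves R
#' unchanged, so the 420 labeled models fall into 210 structurally distinct
#' pairs.
#'
#' @param items condition names (default the 8 body parts).
#' @param sizes category sizes, summing to `length(items)`.
#' @param labels category labels, same length as `sizes`.
#' @param hypothesized named assignment to place first (default
#'   [hypothesized_partition()]).
#' @return character matrix, models x conditions; each row maps every
#'   condition to a category label.
#' @export
enumerate_partitions <- function(items = body_part_conditions(),
                                 sizes = c(4, 2, 2),
                                 labels = c("effector", "face",
                                            "non-effector"),
                                 hypothesized = hypothesized_partition()) {
  if (sum(sizes) != length(items)) .stopf("sizes must sum to the item count")
  if (length(sizes) != length(labels)) .stopf("one label per size")
  n <- length(items)
  first <- utils::combn(n, sizes[1])
  rows <- list()
  for (a in seq_len(ncol(first))) {
    idx1 <- first[, a]
    rest <- setdiff(seq_len(n), idx1)
    second <- utils::combn(length(rest), sizes[2])
    for (b in seq_len(ncol(second))) {
      idx2 <- rest[second[, b]]
      idx3 <- setdiff(rest, idx2)
      row <- character(n)
      row[idx1] <- labels[1]; row[idx2] <- labels[2]; row[idx3] <- labels[3]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- items
  if (!is.null(hypothesized)) {
    hyp <- hypothesized[items]
    hit <- which(apply(out, 1, function(r) all(r == hyp)))
    if (length(hit) != 1)
      .stopf("hypothesized model must appear exactly once in the enumeration")
    out <- rbind(out[hit, , drop = FALSE], out[-hit, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' ANOSIM R statistic for one category partition
#'
#' The M = n(n-1)/2 off-diagonal dissimilarities are ranked (ties take average
#' ranks) and R = (mean between-category rank - mean within-category rank) /
#' (M/2), which lies in `[-1, 1]`; values near 1 indicate strong category
#' separation.
#'
#' @param D dissimilarity matrix over the conditions.
#' @param partition character/factor vector assigning each condition (in the
#'   order of `D`) to a category.
#' @return scalar R.
#' @export
anosim_r <- function(D, partition) {
  n <- nrow(D)
  if (length(partition) != n) .stopf("partition length must match D")
  d <- unclass(D)[lower.tri(D)]
  rk <- rank(d)
  pairs <- which(lower.tri(D), arr.ind = TRUE)
  within <- partition[pairs[, 1]] == partition[pairs[, 2]]
  M <- length(d)
  (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}

# within-pair indicator matrix (pairs x models) for fast exhaustive evaluation
.within_masks <- function(models, n) {
  pairs <- which(lower.tri(diag(n)), arr.ind = TRUE)
  apply(models, 1, function(p) p[pairs[, 1]] == p[pairs[, 2]])
}

#' Exhaustive-permutation ANOSIM test over all category partitions
#'
#' Evaluates the ANOSIM R of every enumerated labeled partition (420 for
#' sizes 4/2/2 over 8 conditions) and reports p = (number of null R values >=
#' the hypothesized model's R) / 420, with the hypothesized model itself
#' included in the count, so the smallest attainable p is 1/420. Because the
#' two size-2 categories are interchangeable for R, a partition whose R
#' strictly exceeds every structurally distinct alternative attains
#' p = 2/420, which rounds to 0.005.
#'
#' @param D dissimilarity matrix.
#' @param hypothesized named category assignment (default
#'   [hypothesized_partition()]).
#' @param models optional precomputed matrix from [enumerate_partitions()]
#'   (hypothesized model in row 1).
#' @return An `anosim_result`: `R` (hypothesized model), `null` (all R values,
#'   hypothesized first), `p`, `n_models`.
#' @export
anosim_test <- function(D, hypothesized = hypothesized_partition(),
                        models = NULL) {
  conds <- rownames(D)
  if (is.null(models))
    models <- enumerate_partitions(items = conds,
                                   hypothesized = hypothesized[conds])
  d <- unclass(D)[lower.tri(D)]
  rk <- rank(d)
  M <- length(d)
  masks <- .within_masks(models, nrow(D))       # pairs x models
  sum_w <- colSums(rk * masks)
  n_w <- colSums(masks)
  r_w <- sum_w / n_w
  r_b <- (sum(rk) - sum_w) / (M - n_w)
  null <- (r_b - r_w) / (M / 2)
  structure(list(R = null[1], null = null,
                 p = mean(null >= null[1]),
                 n_models = length(null)),
            class = "anosim_result")
}

#' Mantel test between two dissimilarity matrices
#'
#' r is the Pearson correlation of the 28 off-diagonal dissimilarities. The
#' null distribution permutes the condition labels of the second matrix:
#' either all 8! = 40,320 relabelings (`scheme = "complete"`, the default for
#' 8 conditions) or a seeded Monte-Carlo sample. The test is one-sided
#' (p = fraction of permuted r >= observed, identity included).
#'
#' @param D1,D2 dissimilarity matrices with the same condition order.
#' @param scheme `"complete"` or `"monte_carlo"`.
#' @param n_mc Monte-Carlo sample size (identity permutation always included).
#' @param seed seed for the Monte-Carlo scheme.
#' @return A `mantel_result`: `r`, `p`, `scheme`, `n_permutations`.
#' @export
mantel_test <- function(D1, D2, scheme = c("complete", "monte_carlo"),
                        n_mc = 9999, seed = 1) {
  scheme <- match.arg(scheme)
  if (!identical(rownames(D1), rownames(D2)))
    .stopf("matrices must share the same condition order")
  n <- nrow(D1)
  v1 <- unclass(D1)[lower.tri(D1)]
  if (stats::sd(v1) == 0 || stats::sd(unclass(D2)[lower.tri(D2)]) == 0)
    .stopf("constant off-diagonal dissimilarities: r undefined")
  M2 <- unclass(D2)
  perms <- if (scheme == "complete") {
    .all_perms(n)
  } else {
    set.seed(as.integer(seed))
    rbind(seq_len(n),
          t(replicate(n_mc, sample.int(n))))
  }
  pairs <- which(lower.tri(D1), arr.ind = TRUE)
  # linear index of the permuted D2 entry for every (perm, pair)
  idx <- perms[, pairs[, 1]] + (perms[, pairs[, 2]] - 1) * n
  V <- matrix(M2[idx], nrow = nrow(perms))
  v1c <- v1 - mean(v1)
  Vc <- V - rowMeans(V)
  rs <- as.numeric(Vc %*% v1c) /
    (sqrt(rowSums(Vc^2)) * sqrt(sum(v1c^2)))
  structure(list(r = rs[1], p = mean(rs >= rs[1]), scheme = scheme,
                 n_permutations = nrow(perms)),
            class = "mantel_result")
}

# all permutations of 1..n as a matrix (n! rows), identity first
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(if (pos > 1) sub[, seq_len(pos - 1), drop = FALSE],
                   n, if (pos <= n - 1) sub[, pos:(n - 1), drop = FALSE])
    out[row:(row + nrow(sub) - 1), ] <- block
    row <- row + nrow(sub)
  }
  # reorder so the identity permutation is first
  id <- which(apply(out, 1, function(p) all(p == seq_len(n))))
  out[c(id, setdiff(seq_len(nrow(out)), id)), , drop = FALSE]
}

#' Within- vs between-group RDM similarity with Fisher-Z ANOVA
#'
#' For every subject, the off-diagonal RDM vector is correlated (Pearson) with
#' (i) the leave-one-out mean RDM of the subject's own group and (ii) the full
#' mean RDM of the other group; the correlations are Fisher-Z transformed and
#' submitted to a two-way ANOVA with factors correlation type
#' (within/between) and group.
#'
#' @param rdms list of subject `rdm` matrices.
#' @param groups factor/character vector of group labels (2 levels), aligned
#'   with `rdms`.
#' @param anova_design `"between"` (default) or `"mixed"` (subject-stratified
#'   error for the within-subject correlation-type factor).
#' @return A `group_similarity_result`: `table` (subject, group, type, r, z)
#'   and `anova` (list of `stat_result` per effect; `A` = type, `B` = group).
#' @export
within_between_similarity <- function(rdms, groups,
                                      anova_design = c("between", "mixed")) {
  anova_design <- match.arg(anova_design)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) .stopf("exactly two groups required")
  if (any(table(groups) < 2)) .stopf("need >= 2 subjects per group")
  n <- length(rdms)
  rows <- vector("list", 2 * n)
  for (s in seq_len(n)) {
    own <- which(groups == groups[s])
    other <- which(groups != groups[s])
    own_mean <- aggregate_rdms(rdms[own], leave_out = match(s, own))
    other_mean <- aggregate_rdms(rdms[other])
    v <- rdm_offdiag(rdms[[s]])
    if (stats::sd(v) == 0) .stopf("degenerate (constant) RDM for subject %d", s)
    r_w <- stats::cor(v, rdm_offdiag(own_mean))
    r_b <- stats::cor(v, rdm_offdiag(other_mean))
    rows[[2 * s - 1]] <- data.frame(subject = s, group = groups[s],
                                    type = "within", r = r_w,
                                    z = fisher_z(r_w))
    rows[[2 * s]] <- data.frame(subject = s, group = groups[s],
                                type = "between", r = r_b,
                                z = fisher_z(r_b))
  }
  tab <- do.call(rbind, rows)
  av <- two_way_anova(tab$z, tab$type, tab$group, design = anova_design,
                      subject = tab$subject)
  structure(list(table = tab, anova = av),
            class = "group_similarity_result")
}

#' Per-subject ANOSIM R values
#'
#' @param rdms list of subject `rdm` matrices.
#' @param hypothesized category assignment.
#' @return numeric vector of R values, one per subject.
#' @export
subject_anosim_r <- function(rdms, hypothesized = hypothesized_partition()) {
  vapply(rdms, function(D) anosim_r(D, hypothesized[rownames(D)]), numeric(1))
}

#' Spearman correlations between subject ANOSIM R and trait scores
#'
#' One Spearman rho per trait column, with Bonferroni correction over the
#' stated family (default 16 = 8 traits x 2 hemispheres).
#'
#' @param subject_r numeric vector of per-subject ANOSIM R values.
#' @param traits data.frame of trait scores (numeric columns are used).
#' @param family Bonferroni family size (default 16).
#' @return data.frame: trait, rho, p, p_bonferroni.
#' @export
trait_correlations <- function(subject_r, traits, family = 16) {
  num <- traits[vapply(traits, is.numeric, logical(1))]
  num$subject <- NULL
  if (nrow(num) != length(subject_r))
    .stopf("traits and subject_r must be aligned")
  rows <- lapply(names(num), function(tr) {
    res <- tryCatch(spearman_bonferroni(subject_r, num[[tr]], family = family),
                    warning = function(w) NULL)
    if (is.null(res))
      data.frame(trait = tr, rho = NA_real_, p = NA_real_,
                 p_bonferroni = NA_real_)
    else
      data.frame(trait = tr, rho = res$statistic, p = res$p,
                 p_bonferroni = res$p_corrected)
  })
  do.call(rbind, rows)
}
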