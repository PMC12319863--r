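#' Stimulus conditions and the hypothesized category partition
#'
#' The experimental design presents 10 stimulus conditions per run. Eight of
#' them are individual body parts entering the representational analyses; the
#' remaining two (whole body, chair) serve the univariate localizer contrast
#' and are excluded from RSA and decoding.
#'
#' @format `bodygeom_conditions()` returns the ordered character vector of all
#'   10 condition names; `body_part_conditions()` the 8 body parts;
#'   `hypothesized_partition()` a named character vector mapping each body part
#'   to its category among `"effector"`, `"non-effector"`, `"face"`.
#' @name conditions
NULL

.COND_ALL <- c("whole body", "chair", "hand", "foot", "arm", "leg",
               "chest", "waist", "upper face", "lower face")
.COND_BODY <- .COND_ALL[3:10]
.CATEGORY <- c(hand = "effector", foot = "effector", arm = "effector",
               leg = "effector", chest = "non-effector",
               waist = "non-effector", `upper face` = "face",
               `lower face` = "face")
.CATEGORY_LEVELS <- c("effector", "face", "non-effector")

#' @rdname conditions
#' @export
bodygeom_conditions <- function() .COND_ALL

#' @rdname conditions
#' @export
body_part_conditions <- function() .COND_BODY

#' @rdname conditions
#' @export
hypothesized_partition <- function() .CATEGORY[.COND_BODY]

# derive a per-subject RNG seed from a master seed; kept within 32-bit range
.subject_seed <- function(seed, subject_index, salt = 0L) {
  as.integer((as.double(seed) + 104729 * subject_index + 15485863 * salt) %%
               2147483647)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_scalar <- function(x, name, nonneg = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a finite numeric scalar", name)
  if (nonneg && x < 0) .stopf("'%s' must be >= 0", name)
  if (integer && x != round(x)) .stopf("'%s' must be an integer", name)
  invisible(x)
}
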