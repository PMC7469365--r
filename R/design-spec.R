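#' Specify the arm structure of a parallel study
#'
#' A design specification fixes the number of arms, their labels, and the
#' number of subjects each arm must receive. Fixing the per-arm sizes fixes
#' the Gram matrix of the treatment contrasts, so that maximizing the full
#' information determinant is equivalent to maximizing the Ds criterion.
#'
#' @param arm_sizes Integer vector of per-arm subject counts `n_1..n_t`
#'   (t >= 2, every entry >= 1). Their sum defines the study size N.
#' @param arm_labels Character vector of `t` distinct arm labels; defaults to
#'   `"A"`, `"B"`, `"C"`, ...
#' @param stratum_arm_counts Optional stratum-by-arm count matrix (rows named
#'   by stratum level, `t` columns) used only by [stratified_randomization()].
#'   Column sums must equal `arm_sizes`.
#'
#' @return An object of class `design_spec`: a list with elements `n_arms`,
#'   `arm_labels`, `arm_sizes`, `n_subjects` and `stratum_arm_counts`.
#'
#' @examples
#' design_spec(c(54, 54, 54))
#' @export
design_spec <- function(arm_sizes, arm_labels = NULL, stratum_arm_counts = NULL) {
  if (length(arm_sizes) < 2) {
    abort("a design needs at least two arms")
  }
  arm_sizes <- as.integer(arm_sizes)
  if (any(is.na(arm_sizes)) || any(arm_sizes < 1)) {
    abort("every arm size must be a positive integer")
  }
  t <- length(arm_sizes)
  if (is.null(arm_labels)) {
    arm_labels <- make_arm_labels(t)
  }
  arm_labels <- as.character(arm_labels)
  if (length(arm_labels) != t || anyDuplicated(arm_labels) || any(!nzchar(arm_labels))) {
    abort("arm_labels must be distinct non-empty labels, one per arm")
  }
  if (!is.null(stratum_arm_counts)) {
    stratum_arm_counts <- as.matrix(stratum_arm_counts)
    if (ncol(stratum_arm_counts) != t) {
      stopf("stratum_arm_counts must have %d columns (one per arm)", t)
    }
    if (is.null(rownames(stratum_arm_counts))) {
      abort("stratum_arm_counts must have stratum levels as row names")
    }
    if (any(stratum_arm_counts < 0) || any(stratum_arm_counts != round(stratum_arm_counts))) {
      abort("stratum_arm_counts must contain non-negative integers")
    }
    if (!all(colSums(stratum_arm_counts) == arm_sizes)) {
      abort("column sums of stratum_arm_counts must equal arm_sizes")
    }
    colnames(stratum_arm_counts) <- arm_labels
  }
  structure(
    list(
      n_arms = t,
      arm_labels = arm_labels,
      arm_sizes = arm_sizes,
      n_subjects = sum(arm_sizes),
      stratum_arm_counts = stratum_arm_counts
    ),
    class = "design_spec"
  )
}

# "A".."Z", then "A1", "B1", ... for implausibly many arms
make_arm_labels <- function(t) {
  if (t <= 26) LETTERS[seq_len(t)] else paste0(LETTERS[(seq_len(t) - 1) %% 26 + 1], (seq_len(t) - 1) %/% 26)
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "<design_spec> %d arms, N = %d (%s)\n",
    x$n_arms, x$n_subjects,
    paste(sprintf("%s:%d", x$arm_labels, x$arm_sizes), collapse = ", ")
  ))
  if (!is.null(x$stratum_arm_counts)) {
    cat(sprintf("  stratified: %d strata with fixed per-stratum arm counts\n",
                nrow(x$stratum_arm_counts)))
  }
  invisible(x)
}

#' Prescribe per-stratum arm counts as even as possible
#'
#' Builds the stratum-by-arm count table a stratified randomization needs:
#' each stratum's subjects are spread over the arms so that within-stratum
#' counts differ by at most one, while column totals match the per-arm sizes
#' exactly. Remainder units go to the arms with the largest unfilled capacity
#' (ties to the earlier arm), a largest-remainder apportionment.
#'
#' @param strata Character (or factor) vector of per-subject stratum labels,
#'   length N.
#' @param spec A [design_spec()] whose `n_subjects` equals `length(strata)`.
#'
#' @return An integer matrix, strata (levels of `strata`) by arms, suitable as
#'   the `stratum_arm_counts` field of [design_spec()].
#' @examples
#' spec <- design_spec(c(3, 3))
#' even_stratum_counts(rep(c("g1", "g2"), c(4, 2)), spec)
#' @export
even_stratum_counts <- function(strata, spec) {
  strata <- as.character(strata)
  if (length(strata) != spec$n_subjects) {
    stopf("strata has %d entries but the design has %d subjects", length(strata), spec$n_subjects)
  }
  levels <- unique(strata)
  sizes <- as.integer(table(factor(strata, levels = levels)))
  t <- spec$n_arms
  counts <- matrix(sizes %/% t, nrow = length(levels), ncol = t,
                   dimnames = list(levels, spec$arm_labels))
  remaining <- spec$arm_sizes - colSums(counts)
  for (s in seq_along(levels)) {
    extra <- sizes[s] %% t
    if (extra > 0) {
      pick <- order(remaining, decreasing = TRUE)[seq_len(extra)]
      counts[s, pick] <- counts[s, pick] + 1L
      remaining[pick] <- remaining[pick] - 1L
    }
  }
  if (any(remaining != 0)) {
    abort("could not apportion strata evenly to the prescribed arm sizes")
  }
  counts
}
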