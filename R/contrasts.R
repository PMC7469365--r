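#' Orthonormal Helmert contrast matrix
#'
#' Returns the t x (t-1) matrix whose columns are unit-norm, mutually
#' orthogonal, and orthogonal to the all-ones vector: column j contrasts
#' level j+1 against the mean of levels 1..j. This deterministic family is
#' the contrast parameterization used throughout the package; any other
#' full-rank contrast family spans the same space and gives the same
#' Ds-efficiency.
#'
#' @param t Number of arms (>= 2).
#' @return A `t` x `t-1` numeric matrix `H` with `t(H) %*% H` = identity.
#' @examples
#' helmert_contrasts(3)
#' @export
helmert_contrasts <- function(t) {
  t <- as.integer(t)
  if (is.na(t) || t < 2) abort("t must be an integer >= 2")
  H <- matrix(0, t, t - 1)
  for (j in seq_len(t - 1)) {
    H[seq_len(j), j] <- 1 / sqrt(j * (j + 1))
    H[j + 1, j] <- -j / sqrt(j * (j + 1))
  }
  H
}

# Scaled contrast rows: row k is the treatment-contrast row of every subject
# in arm k. The sqrt(t) scaling makes each column of T have squared norm N
# when the arms are of equal size, so |T'T| = N^(t-1) exactly.
contrast_rows <- function(t) sqrt(t) * helmert_contrasts(t)

#' Treatment contrast matrix of an allocation
#'
#' Builds the N x (t-1) matrix T modelling the differences between the arms:
#' row i is the scaled Helmert row of the arm subject i is allocated to
#' (`sqrt(t)` times row `arm_of[i]` of [helmert_contrasts()]). Every column is
#' orthogonal to the intercept. For equal arm sizes `t(T) %*% T = N * I`, so
#' the Gram determinant attains its upper bound `N^(t-1)`; for unequal sizes
#' the determinant is strictly smaller (arithmetic-geometric mean inequality)
#' and is fixed by the arm sizes alone.
#'
#' @param arm_of Integer vector of length N mapping each subject to an arm
#'   index in `1..t`.
#' @param spec A [design_spec()]; the allocation must realize its arm sizes
#'   exactly.
#' @return An N x (t-1) numeric matrix.
#' @examples
#' spec <- design_spec(c(3, 3))
#' treatment_contrasts(rep(1:2, each = 3), spec)
#' @export
treatment_contrasts <- function(arm_of, spec) {
  arm_of <- check_allocation(arm_of, spec)
  contrast_rows(spec$n_arms)[arm_of, , drop = FALSE]
}

# Validates an allocation against a design_spec; returns it as integer.
check_allocation <- function(arm_of, spec) {
  arm_of <- as.integer(arm_of)
  if (length(arm_of) != spec$n_subjects || anyNA(arm_of) ||
      any(arm_of < 1L) || any(arm_of > spec$n_arms)) {
    stopf("allocation must map %d subjects to arm indices 1..%d",
          spec$n_subjects, spec$n_arms)
  }
  counts <- tabulate(arm_of, nbins = spec$n_arms)
  if (!all(counts == spec$arm_sizes)) {
    stopf("allocation arm counts (%s) do not match the design arm sizes (%s)",
          paste(counts, collapse = ","), paste(spec$arm_sizes, collapse = ","))
  }
  arm_of
}
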