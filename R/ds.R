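#' The Ds criterion of an allocation
#'
#' Computes the determinant of the residual sums-of-squares-and-products
#' matrix of the treatment contrasts after regressing them on the covariates:
#' `Ds = |T'T - (B'T)'(B'T)|`, where `B` is an orthonormal basis of the column
#' space of the covariate matrix X. This equals `|T'(I - X(X'X)^-1 X')T|` when
#' X has full column rank, but remains well-defined for rank-deficient
#' encodings (e.g. full-dummy coding) because only the column space enters.
#' The criterion is proportional to the precision of the covariate-adjusted
#' arm-effect estimators; maximizing it over allocations is the package's
#' purpose.
#'
#' The determinant is evaluated through the eigenvalues of the symmetric
#' (t-1) x (t-1) residual matrix; eigenvalues in `[-1e-10 * N^(t-1), 0]` are
#' clamped to zero (an exactly aliased contrast), anything more negative is an
#' internal error.
#'
#' @param X A [encode_covariates()] result (`covariate_matrix`).
#' @param T_mat An N x (t-1) contrast matrix from [treatment_contrasts()].
#' @return An object of class `ds_eval`: list with `ds_value`, `log_ds`
#'   (natural log, `-Inf` allowed), `ds_efficiency` (in `[0, 1]`), `t`, and
#'   `n`.
#' @examples
#' toy <- generate_toy(seed = 1, N = 9, t = 3)
#' X <- encode_covariates(toy$table, continuous = "x1")
#' Tm <- treatment_contrasts(rep(1:3, each = 3), toy$spec)
#' ds_criterion(X, Tm)
#' @export
ds_criterion <- function(X, T_mat) {
  if (!inherits(X, "covariate_matrix")) abort("X must be a covariate_matrix")
  T_mat <- as.matrix(T_mat)
  if (nrow(T_mat) != X$n) {
    stopf("X has %d rows but T has %d", X$n, nrow(T_mat))
  }
  t <- ncol(T_mat) + 1L
  P <- crossprod(X$basis, T_mat)
  M <- crossprod(T_mat) - crossprod(P)
  ds_eval_from_gram(M, n = X$n, t = t)
}

# Shared constructor: residual Gram matrix -> ds_eval.
ds_eval_from_gram <- function(M, n, t) {
  d <- det_psd(M, tol_scale = as.double(n)^(t - 1))
  structure(
    list(
      ds_value = d$det,
      log_ds = d$logdet,
      ds_efficiency = ds_efficiency(d$det, N = n, t = t),
      t = t,
      n = n
    ),
    class = "ds_eval"
  )
}

#' Ds-efficiency of a study design with respect to its covariates
#'
#' Normalizes the Ds criterion to the unit scale:
#' `ds_value^(1/(t-1)) / N`. The value is 1 when the treatment contrasts are
#' orthogonal to every covariate (the attainable maximum for equal arm sizes,
#' since `|T'T| = N^(t-1)` then), and 0 when a treatment contrast is
#' completely aliased with the covariate column space. For unequal arm sizes
#' the optimum is below 1 by the size imbalance alone.
#'
#' @param ds_value Non-negative Ds criterion value.
#' @param N Number of subjects (N >= t).
#' @param t Number of arms (t >= 2).
#' @return A number in `[0, 1]`.
#' @examples
#' ds_efficiency(162^2, N = 162, t = 3)  # 1
#' @export
ds_efficiency <- function(ds_value, N, t) {
  if (ds_value < 0 || t < 2 || N < t) {
    abort("need ds_value >= 0, t >= 2 and N >= t")
  }
  ds_value^(1 / (t - 1)) / N
}

#' Ds criterion via the determinant ratio (full-rank oracle)
#'
#' Computes the same quantity as [ds_criterion()] in its determinant-ratio
#' form `|F'F| / |X'X|` with `F = [X T]`. This form requires a full-column-
#' rank X (drop dependent columns first) and exists as an independent
#' cross-check of the projection form; the optimizer never uses it.
#'
#' @param X_full_rank Plain numeric matrix with full column rank.
#' @param T_mat N x (t-1) contrast matrix.
#' @return The Ds criterion value (a number).
#' @examples
#' Tm <- treatment_contrasts(rep(1:2, each = 3), design_spec(c(3, 3)))
#' ds_via_ratio(matrix(1, 6, 1), Tm)  # 6: orthogonal case
#' @export
ds_via_ratio <- function(X_full_rank, T_mat) {
  X <- as.matrix(X_full_rank)
  T_mat <- as.matrix(T_mat)
  if (nrow(X) != nrow(T_mat)) abort("X and T must have the same number of rows")
  XtX <- crossprod(X)
  if (qr(XtX)$rank < ncol(X)) {
    abort("X'X is singular; drop dependent columns or use ds_criterion(), which handles rank deficiency")
  }
  F_mat <- cbind(X, T_mat)
  det(crossprod(F_mat)) / det(XtX)
}

# Fast path used by the optimizer and Monte-Carlo loops: evaluate the Ds
# criterion of an allocation from per-arm sums of the basis rows, avoiding
# the N x (t-1) contrast matrix entirely.
ds_from_arms <- function(basis, arm_of, spec) {
  Hs <- contrast_rows(spec$n_arms)
  # arms all present (sizes >= 1), so rowsum's groups are 1..t in order
  A <- rowsum(basis, group = arm_of)                 # t x r per-arm sums
  P <- crossprod(A, Hs)                              # r x (t-1) = B'T
  TtT <- crossprod(Hs, Hs * spec$arm_sizes)
  ds_eval_from_gram(TtT - crossprod(P), n = spec$n_subjects, t = spec$n_arms)
}

#' @export
print.ds_eval <- function(x, ...) {
  cat(sprintf("<ds_eval> Ds = %.6g, Ds-efficiency = %.4f (N = %d, t = %d)\n",
              x$ds_value, x$ds_efficiency, x$n, x$t))
  invisible(x)
}

#' @rdname ds_criterion
#' @param x A `ds_eval` object.
#' @param ... Unused.
#' @method glance ds_eval
#' @export
glance.ds_eval <- function(x, ...) {
  tibble::tibble(
    ds_value = x$ds_value,
    log_ds = x$log_ds,
    ds_efficiency = x$ds_efficiency,
    n = x$n,
    t = x$t
  )
}
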