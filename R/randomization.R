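#' Completely random allocation with fixed arm sizes
#'
#' Uniform draw over all allocations realizing the prescribed per-arm sizes.
#' Identical contract to [initial_allocation()]; exposed separately because it
#' is the "complete randomization" baseline of the Monte-Carlo comparison,
#' not an optimizer internal. (Per-subject coin flips would not keep `|T'T|`
#' fixed; the fixed-size interpretation is what the efficiency normalization
#' presupposes.)
#'
#' @inheritParams initial_allocation
#' @return Integer allocation vector of length N.
#' @export
complete_randomization <- function(spec, seed = NULL) {
  initial_allocation(spec, seed = seed)
}

#' Stratified random allocation with fixed per-stratum arm counts
#'
#' Within each stratum (e.g. first-visit group), assigns subjects to arms
#' uniformly at random among the assignments that realize exactly the
#' prescribed stratum-by-arm counts; strata are drawn independently. Use
#' [even_stratum_counts()] to prescribe counts "as even as possible".
#'
#' @param spec A [design_spec()] whose `stratum_arm_counts` is set.
#' @param strata Per-subject stratum labels (length N); the set of levels
#'   must equal the row names of `spec$stratum_arm_counts`.
#' @param seed Optional integer seed.
#' @return Integer allocation vector of length N.
#' @examples
#' strata <- rep(c("g1", "g2"), c(4, 2))
#' spec <- design_spec(c(3, 3))
#' spec <- design_spec(c(3, 3), stratum_arm_counts = even_stratum_counts(strata, spec))
#' stratified_randomization(spec, strata, seed = 1)
#' @export
stratified_randomization <- function(spec, strata, seed = NULL) {
  counts <- spec$stratum_arm_counts
  if (is.null(counts)) {
    abort("spec has no stratum_arm_counts; build one with even_stratum_counts()")
  }
  strata <- as.character(strata)
  if (length(strata) != spec$n_subjects) {
    stopf("strata has %d entries but the design has %d subjects",
          length(strata), spec$n_subjects)
  }
  if (!setequal(unique(strata), rownames(counts))) {
    abort("the stratum levels in `strata` must match the rows of stratum_arm_counts")
  }
  sizes <- table(factor(strata, levels = rownames(counts)))
  bad <- which(rowSums(counts) != as.integer(sizes))
  if (length(bad)) {
    stopf("stratum '%s' has %d subjects but its prescribed arm counts sum to %d",
          rownames(counts)[bad[1]], sizes[bad[1]], rowSums(counts)[bad[1]])
  }
  with_seed_(seed, {
    arm_of <- integer(spec$n_subjects)
    for (s in rownames(counts)) {
      members <- which(strata == s)
      pool <- rep.int(seq_len(spec$n_arms), counts[s, ])
      arm_of[members] <- pool[sample.int(length(pool))]
    }
    arm_of
  })
}

#' Monte-Carlo distribution of Ds-efficiencies under randomization
#'
#' Draws `n_draws` independent random allocations (complete or stratified),
#' evaluates the Ds-efficiency of each against the fixed covariate matrix,
#' and summarizes the distribution: empirical middle-95% interval (2.5th and
#' 97.5th percentiles, linear interpolation between order statistics),
#' minimum and maximum. This is the yardstick against which the exchange
#' optimizer is compared.
#'
#' @param X A [encode_covariates()] result.
#' @param spec A [design_spec()] (with `stratum_arm_counts` for the
#'   stratified method).
#' @param method `"complete"` or `"stratified"`.
#' @param strata Per-subject stratum labels, required for `"stratified"`.
#' @param n_draws Number of random allocations (>= 100; default 10000).
#' @param seed Optional integer seed; the full efficiencies vector is
#'   reproducible bitwise given the seed.
#' @return An object of class `mc_summary`: list with `n_draws`,
#'   `efficiencies`, `interval_95` (named lower/upper), `minimum`, `maximum`,
#'   `method` and `seed`. Use [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' toy <- generate_toy(seed = 5, N = 12, t = 3)
#' X <- encode_covariates(toy$table, continuous = "x1")
#' mc <- monte_carlo(X, toy$spec, n_draws = 200, seed = 9)
#' glance(mc)
#' @export
monte_carlo <- function(X, spec, method = c("complete", "stratified"),
                        strata = NULL, n_draws = 10000, seed = NULL) {
  method <- match.arg(method)
  if (!inherits(X, "covariate_matrix")) abort("X must be a covariate_matrix")
  if (n_draws < 100) abort("n_draws must be >= 100")
  if (method == "stratified" && is.null(strata)) {
    abort("the stratified method needs per-subject `strata` labels")
  }
  effs <- with_seed_(seed, {
    vapply(seq_len(n_draws), function(d) {
      arm_of <- if (method == "complete") {
        complete_randomization(spec)
      } else {
        stratified_randomization(spec, strata)
      }
      ds_from_arms(X$basis, arm_of, spec)$ds_efficiency
    }, numeric(1))
  })
  q <- quantile(effs, c(0.025, 0.975), names = FALSE, type = 7)
  structure(
    list(
      n_draws = as.integer(n_draws),
      efficiencies = effs,
      interval_95 = c(lower = q[1], upper = q[2]),
      minimum = min(effs),
      maximum = max(effs),
      method = method,
      seed = seed
    ),
    class = "mc_summary"
  )
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf(
    "<mc_summary> %s randomization, %d draws\n  Ds-efficiency middle-95%%: [%.3f, %.3f]  min %.3f  max %.3f\n",
    x$method, x$n_draws, x$interval_95["lower"], x$interval_95["upper"],
    x$minimum, x$maximum
  ))
  invisible(x)
}

#' Per-draw tibble of a Monte-Carlo efficiency distribution
#'
#' @param x An `mc_summary` object.
#' @param ... Unused.
#' @return A tibble with columns `draw` and `ds_efficiency`.
#' @method tidy mc_summary
#' @export
tidy.mc_summary <- function(x, ...) {
  tibble::tibble(draw = seq_len(x$n_draws), ds_efficiency = x$efficiencies)
}

#' One-row summary of a Monte-Carlo efficiency distribution
#'
#' @param x An `mc_summary` object.
#' @param ... Unused.
#' @return A tibble with the method, draw count, interval endpoints and
#'   extremes.
#' @method glance mc_summary
#' @export
glance.mc_summary <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_draws = x$n_draws,
    lower_95 = unname(x$interval_95["lower"]),
    upper_95 = unname(x$interval_95["upper"]),
    minimum = x$minimum,
    maximum = x$maximum,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
}

#' Histogram of a Monte-Carlo Ds-efficiency distribution
#'
#' @param object An `mc_summary` object.
#' @param reference Optional Ds-efficiency (e.g. the optimizer's) drawn as a
#'   vertical line for comparison.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_summary
#' @export
autoplot.mc_summary <- function(object, reference = NULL, bins = 60, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$ds_efficiency)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$interval_95, linetype = "dashed") +
    ggplot2::labs(
      x = "Ds-efficiency",
      y = "allocations",
      title = sprintf("%s randomization (%d draws)", object$method, object$n_draws),
      subtitle = sprintf("middle 95%%: [%.3f, %.3f]",
                         object$interval_95["lower"], object$interval_95["upper"])
    )
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_vline(xintercept = reference, colour = "red", linewidth = 1)
  }
  p
}

#' Write a Monte-Carlo efficiencies vector to CSV
#'
#' One column named `ds_efficiency`, one row per draw — the raw material for
#' external plotting of the efficiency distribution.
#'
#' @param mc An `mc_summary` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_efficiencies <- function(mc, path) {
  readr::write_csv(tibble::tibble(ds_efficiency = mc$efficiencies), path)
  invisible(path)
}
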