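#' Parameters for the synthetic trial-replica covariate table
#'
#' Defaults emulate the covariate structure of the motivating three-arm
#' nutrition trial: 162 subjects (104 female, 58 male), 17 first-visit groups,
#' and continuous covariates age (years), BMI (kg/m2) and a composite health
#' score (dimensionless) with pooled normal parameters. The published
#' per-group sizes are not reliably recoverable from the source tables, so
#' the default `group_sizes` is a synthetic stand-in — 17 groups in the
#' plausible 6–12 range summing to 162 — and fully overridable.
#'
#' @param n_subjects Total subjects (default 162).
#' @param n_female,n_male Gender counts (defaults 104 and 58; must sum to
#'   `n_subjects`).
#' @param group_sizes Integer vector of first-visit-group sizes summing to
#'   `n_subjects` (default: the 17-group stand-in).
#' @param age_mean,age_sd Age distribution in years (defaults 42.6, 12.3).
#' @param bmi_mean,bmi_sd BMI distribution in kg/m2 (defaults 25.3, 3.6).
#' @param score_mean,score_sd Health-score distribution (defaults 1.476,
#'   0.13).
#' @param correlation Optional 3x3 correlation matrix for (age, BMI, score),
#'   for sensitivity studies; default independent.
#' @param seed Optional integer seed.
#' @return A list of class `replica_params`.
#' @export
replica_params <- function(n_subjects = 162,
                           n_female = 104,
                           n_male = 58,
                           group_sizes = c(10, 10, 11, 7, 11, 10, 7, 11, 8, 9, 9, 11, 10, 10, 12, 6, 10),
                           age_mean = 42.6, age_sd = 12.3,
                           bmi_mean = 25.3, bmi_sd = 3.6,
                           score_mean = 1.476, score_sd = 0.13,
                           correlation = NULL,
                           seed = NULL) {
  p <- list(
    n_subjects = as.integer(n_subjects),
    n_female = as.integer(n_female),
    n_male = as.integer(n_male),
    group_sizes = as.integer(group_sizes),
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    score_mean = score_mean, score_sd = score_sd,
    correlation = correlation,
    seed = seed
  )
  if (p$n_female + p$n_male != p$n_subjects) {
    abort("n_female + n_male must equal n_subjects")
  }
  if (sum(p$group_sizes) != p$n_subjects || any(p$group_sizes < 1)) {
    abort("group_sizes must be positive and sum to n_subjects")
  }
  if (any(c(p$age_sd, p$bmi_sd, p$score_sd) <= 0)) {
    abort("all standard deviations must be positive")
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!all(dim(correlation) == c(3, 3)) || !isSymmetric(correlation) ||
        any(abs(diag(correlation) - 1) > 1e-12)) {
      abort("correlation must be a symmetric 3x3 matrix with unit diagonal")
    }
    p$correlation <- correlation
  }
  structure(p, class = "replica_params")
}

# Normal draw truncated to [lo, hi] by redrawing out-of-range values.
# Truncation bounds are wide (several sd), so moments shift negligibly.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  repeat {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) return(x)
    x[bad] <- rnorm(length(bad), mean, sd)
  }
}

#' Generate a synthetic replica of the motivating trial's covariate table
#'
#' Produces a subject table with exactly the prescribed gender counts and
#' first-visit-group sizes (gender randomly interleaved across groups), and
#' continuous covariates drawn from the pooled normal parameters: age
#' truncated to [18, 70] years, BMI truncated to [18, 40] kg/m2, health score
#' untruncated. Per-arm near-equality of the covariate summaries is then an
#' output of a good allocation, not an input of the generator.
#'
#' @param params A [replica_params()] object (its `seed` field drives all
#'   randomness; the same params give the identical table).
#' @return A tibble with columns `subject_id`, `gender` ("F"/"M"),
#'   `visit_group` ("1".."17" by default), `age`, `bmi`, `score`.
#' @examples
#' replica <- generate_trial_replica(replica_params(seed = 42))
#' table(replica$gender)
#' @export
generate_trial_replica <- function(params = replica_params()) {
  if (!inherits(params, "replica_params")) {
    abort("params must come from replica_params()")
  }
  n <- params$n_subjects
  with_seed_(params$seed, {
    gender_pool <- rep(c("F", "M"), c(params$n_female, params$n_male))
    cont <- if (is.null(params$correlation)) {
      cbind(
        age = rnorm_trunc(n, params$age_mean, params$age_sd, 18, 70),
        bmi = rnorm_trunc(n, params$bmi_mean, params$bmi_sd, 18, 40),
        score = rnorm(n, params$score_mean, params$score_sd)
      )
    } else {
      # correlated draws via Cholesky; truncation applied afterwards distorts
      # the correlation slightly at the bounds
      Z <- matrix(rnorm(3 * n), n, 3) %*% chol(params$correlation)
      cbind(
        age = pmin(pmax(params$age_mean + params$age_sd * Z[, 1], 18), 70),
        bmi = pmin(pmax(params$bmi_mean + params$bmi_sd * Z[, 2], 18), 40),
        score = params$score_mean + params$score_sd * Z[, 3]
      )
    }
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      gender = gender_pool[sample.int(n)],
      visit_group = as.character(rep(seq_along(params$group_sizes), params$group_sizes)),
      age = cont[, "age"],
      bmi = cont[, "bmi"],
      score = cont[, "score"]
    )
  })
}

#' Generate a toy subject table and design for oracle-scale testing
#'
#' Small instances whose allocation space is enumerable: standard-normal
#' continuous covariates, categorical levels assigned round-robin and then
#' shuffled, and arm sizes as equal as possible (differing by at most one).
#'
#' @param seed Optional integer seed.
#' @param N Number of subjects.
#' @param t Number of arms (t <= N).
#' @param n_continuous Number of continuous covariates `x1..xk` (default 1).
#' @param n_categorical_levels Integer vector: one entry per categorical
#'   covariate `c1..cm`, giving its number of levels (default none).
#' @return A list with `table` (tibble) and `spec` (a [design_spec()]).
#' @examples
#' generate_toy(seed = 1, N = 10, t = 3)$spec
#' @export
generate_toy <- function(seed = NULL, N, t, n_continuous = 1, n_categorical_levels = integer()) {
  if (t > N) stopf("cannot form %d arms from %d subjects", t, N)
  sizes <- rep(N %/% t, t)
  extra <- N %% t
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  tab <- with_seed_(seed, {
    out <- tibble::tibble(subject_id = sprintf("S%02d", seq_len(N)))
    for (k in seq_len(n_continuous)) {
      out[[paste0("x", k)]] <- rnorm(N)
    }
    for (m in seq_along(n_categorical_levels)) {
      lev <- paste0("L", seq_len(n_categorical_levels[m]))
      out[[paste0("c", m)]] <- rep_len(lev, N)[sample.int(N)]
    }
    out
  })
  list(table = tab, spec = design_spec(sizes))
}
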