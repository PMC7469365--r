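#' Draw a uniformly random allocation with fixed arm sizes
#'
#' Shuffles the fixed multiset of arm indices (`n_k` copies of arm k) over
#' the subjects, giving a uniform draw over all allocations that realize the
#' prescribed arm sizes. This is both the optimizer's random starting point
#' and the "completely random allocation" baseline.
#'
#' @param spec A [design_spec()].
#' @param seed Optional integer seed; the same seed always yields the same
#'   allocation and the caller's RNG state is left untouched.
#' @return Integer vector of length N with arm indices in `1..t`.
#' @examples
#' initial_allocation(design_spec(c(2, 2)), seed = 1)
#' @export
initial_allocation <- function(spec, seed = NULL) {
  pool <- rep.int(seq_len(spec$n_arms), spec$arm_sizes)
  with_seed_(seed, pool[sample.int(spec$n_subjects)])
}

#' Optimizer state for incremental Ds bookkeeping
#'
#' Packages the quantities the exchange search maintains: the allocation, the
#' projected contrasts `P = B'T` (r x (t-1)), the residual Gram matrix
#' `M = T'T - P'P`, and the current Ds value. Swapping two subjects between
#' arms changes only two rows of T, so P changes by a rank-one update and the
#' Ds value by a closed-form rank-two determinant update — the state makes
#' that update cheap.
#'
#' @param X A [encode_covariates()] result.
#' @param arm_of Allocation vector satisfying `spec`.
#' @param spec A [design_spec()].
#' @return An object of class `optimizer_state`.
#' @export
optimizer_state <- function(X, arm_of, spec) {
  if (!inherits(X, "covariate_matrix")) abort("X must be a covariate_matrix")
  if (X$n != spec$n_subjects) stopf("X has %d rows but the design expects %d", X$n, spec$n_subjects)
  arm_of <- check_allocation(arm_of, spec)
  Hs <- contrast_rows(spec$n_arms)
  A <- rowsum(X$basis, group = arm_of)
  P <- crossprod(A, Hs)
  TtT <- crossprod(Hs, Hs * spec$arm_sizes)
  M <- TtT - crossprod(P)
  structure(
    list(
      arm_of = arm_of,
      spec = spec,
      basis = X$basis,
      Hs = Hs,
      TtT = TtT,
      projected_contrasts = P,
      gram = M,
      current_ds = det_psd(M, tol_scale = as.double(X$n)^(spec$n_arms - 1))$det
    ),
    class = "optimizer_state"
  )
}

#' Ds change from swapping two subjects between arms
#'
#' Returns `Ds(after swapping i and j) - Ds(before)` without mutating the
#' state. Only rows i and j of T change, so `P = B'T` receives the rank-one
#' update `(b_i - b_j)(h_b - h_a)'` and the residual Gram matrix a symmetric
#' rank-two update whose determinant is evaluated in closed form through the
#' matrix determinant lemma. When the current residual matrix is singular
#' (Ds = 0), the delta is computed by direct recomputation instead.
#'
#' @param state An [optimizer_state()].
#' @param i,j Subject indices (1-based) in different arms.
#' @return The Ds difference (a number).
#' @export
swap_delta <- function(state, i, j) {
  a <- state$arm_of[i]
  b <- state$arm_of[j]
  if (a == b) stopf("subjects %d and %d are in the same arm; a swap would be a no-op", i, j)
  M <- state$gram
  detM <- state$current_ds
  scale <- as.double(nrow(state$basis))^(state$spec$n_arms - 1)
  if (detM <= 1e-12 * scale) {
    # singular residual matrix: the capacitance form needs M^-1; recompute
    arm2 <- state$arm_of
    arm2[c(i, j)] <- c(b, a)
    return(ds_from_arms(state$basis, arm2, state$spec)$ds_value - detM)
  }
  u <- state$Hs[b, ] - state$Hs[a, ]
  d <- state$basis[i, ] - state$basis[j, ]
  v <- drop(crossprod(state$projected_contrasts, d))
  s <- sum(d * d)
  w <- v + (s / 2) * u
  Minv <- solve(M)
  z <- drop(Minv %*% u)
  alpha <- sum(u * z)
  cc <- sum(z * v) + (s / 2) * alpha
  beta <- sum(w * drop(Minv %*% w))
  detM * ((1 - cc)^2 - alpha * beta) - detM
}

# Applies an accepted swap: rank-one update of P, fresh (t-1)^2 Gram.
apply_swap <- function(state, i, j) {
  a <- state$arm_of[i]
  b <- state$arm_of[j]
  u <- state$Hs[b, ] - state$Hs[a, ]
  d <- state$basis[i, ] - state$basis[j, ]
  state$projected_contrasts <- state$projected_contrasts + outer(d, u)
  state$arm_of[c(i, j)] <- c(b, a)
  state$gram <- state$TtT - crossprod(state$projected_contrasts)
  state$current_ds <- det_psd(
    state$gram,
    tol_scale = as.double(nrow(state$basis))^(state$spec$n_arms - 1)
  )$det
  state
}

# One steepest-ascent pass: evaluate the Ds delta of every cross-arm pair
# (vectorized per arm pair over the full swap grid) and return the best swap.
# Ties break toward the lexicographically smallest (min(i,j), max(i,j)).
best_swap <- function(state, G) {
  arms <- state$arm_of
  t <- state$spec$n_arms
  M <- state$gram
  detM <- state$current_ds
  scale <- as.double(nrow(state$basis))^(t - 1)
  singular <- detM <= 1e-12 * scale
  if (!singular) {
    Minv <- solve(M)
    W <- state$basis %*% state$projected_contrasts     # N x (t-1), row i = P'b_i
    Q <- W %*% Minv %*% t(W)                           # N x N, v'M^-1 v pieces
    Qd <- diag(Q)
  }
  Gd <- diag(G)
  best <- list(delta = -Inf, i = 0L, j = 0L)
  idx <- lapply(seq_len(t), function(k) which(arms == k))
  for (a in seq_len(t - 1)) {
    for (b in seq(a + 1, t)) {
      Ia <- idx[[a]]
      Ib <- idx[[b]]
      s_grid <- outer(Gd[Ia], Gd[Ib], "+") - 2 * G[Ia, Ib, drop = FALSE]
      if (singular) {
        delta <- matrix(NA_real_, length(Ia), length(Ib))
        for (ii in seq_along(Ia)) {
          for (jj in seq_along(Ib)) {
            delta[ii, jj] <- swap_delta(state, Ia[ii], Ib[jj])
          }
        }
      } else {
        u <- state$Hs[b, ] - state$Hs[a, ]
        z <- drop(Minv %*% u)
        alpha <- sum(u * z)
        Wz <- drop(W %*% z)
        uMv <- outer(Wz[Ia], Wz[Ib], "-")
        cc <- uMv + (s_grid / 2) * alpha
        vMv <- outer(Qd[Ia], Qd[Ib], "+") - 2 * Q[Ia, Ib, drop = FALSE]
        beta <- vMv + s_grid * uMv + (s_grid^2 / 4) * alpha
        delta <- detM * ((1 - cc)^2 - alpha * beta - 1)
      }
      m <- max(delta)
      if (m >= best$delta) {
        hits <- which(delta == m, arr.ind = TRUE)
        ii <- Ia[hits[, 1]]
        jj <- Ib[hits[, 2]]
        lo <- pmin(ii, jj)
        hi <- pmax(ii, jj)
        pick <- order(lo, hi)[1]
        cand <- list(delta = m, i = ii[pick], j = jj[pick])
        if (m > best$delta ||
            (min(cand$i, cand$j) < min(best$i, best$j)) ||
            (min(cand$i, cand$j) == min(best$i, best$j) &&
             max(cand$i, cand$j) < max(best$i, best$j))) {
          best <- cand
        }
      }
    }
  }
  best
}

#' Maximize the Ds criterion by restart-based pairwise exchange
#'
#' From each of `n_restarts` uniformly random starting allocations, repeatedly
#' scans all cross-arm subject pairs and applies the best-improving swap
#' (relative improvement threshold `1e-10`; ties break toward the
#' lexicographically smallest pair) until a full scan yields no improvement,
#' then returns the best local optimum over restarts. Pairwise exchanges
#' preserve the per-arm sizes by construction, so `|T'T|` stays fixed and
#' maximizing Ds is equivalent to maximizing the full information determinant.
#' Deterministic given `seed`: one master seed spawns per-restart seeds by a
#' fixed counter scheme.
#'
#' @param X A [encode_covariates()] result.
#' @param spec A [design_spec()] with `n_subjects == X$n`.
#' @param n_restarts Number of random restarts (default 50).
#' @param seed Optional integer master seed.
#' @param quiet Suppress per-restart progress messages (default TRUE).
#' @return An object of class `ds_optim`: list with `arm_of` (integer
#'   allocation), `evaluation` (a `ds_eval`), `n_restarts_run`,
#'   `n_swaps_accepted`, `seed`, `spec` and `subject_id`. Use [tidy()] for a
#'   per-subject tibble and [glance()] for a one-row summary.
#' @examples
#' toy <- generate_toy(seed = 3, N = 9, t = 3)
#' X <- encode_covariates(toy$table, continuous = "x1")
#' fit <- exchange_optimize(X, toy$spec, n_restarts = 5, seed = 1)
#' glance(fit)
#' @export
exchange_optimize <- function(X, spec, n_restarts = 50, seed = NULL, quiet = TRUE) {
  if (!inherits(X, "covariate_matrix")) abort("X must be a covariate_matrix")
  if (X$n != spec$n_subjects) {
    stopf("X has %d rows but the design expects %d subjects", X$n, spec$n_subjects)
  }
  if (n_restarts < 1) abort("n_restarts must be >= 1")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  seeds <- spawn_seeds(seed, n_restarts)
  G <- tcrossprod(X$basis)
  scale <- as.double(X$n)^(spec$n_arms - 1)
  best_state <- NULL
  n_swaps <- 0L
  for (k in seq_len(n_restarts)) {
    state <- optimizer_state(X, initial_allocation(spec, seed = seeds[k]), spec)
    repeat {
      sw <- best_swap(state, G)
      if (sw$delta <= 1e-10 * max(state$current_ds, scale * 1e-8)) break
      state <- apply_swap(state, sw$i, sw$j)
      n_swaps <- n_swaps + 1L
    }
    if (is.null(best_state) || state$current_ds > best_state$current_ds) {
      best_state <- state
    }
    if (!quiet) {
      message(sprintf("restart %d/%d: best Ds-efficiency so far %.4f",
                      k, n_restarts,
                      ds_efficiency(best_state$current_ds, X$n, spec$n_arms)))
    }
  }
  structure(
    list(
      arm_of = best_state$arm_of,
      evaluation = ds_from_arms(X$basis, best_state$arm_of, spec),
      n_restarts_run = n_restarts,
      n_swaps_accepted = n_swaps,
      seed = seed,
      spec = spec,
      subject_id = X$subject_id
    ),
    class = "ds_optim"
  )
}

#' Exact Ds maximization by exhaustive enumeration
#'
#' Enumerates every distinct assignment of subjects to (distinguishable) arms
#' with the prescribed sizes and returns the maximizer; ties report the first
#' assignment in enumeration (lexicographic) order. A guard rejects problems
#' with more than 200,000 assignments. Intended as a test oracle for
#' [exchange_optimize()] on small instances.
#'
#' @inheritParams exchange_optimize
#' @return A `ds_optim` object (with `n_restarts_run = NA`).
#' @examples
#' toy <- generate_toy(seed = 3, N = 6, t = 2)
#' X <- encode_covariates(toy$table, continuous = "x1")
#' brute_force_optimize(X, toy$spec)$evaluation
#' @export
brute_force_optimize <- function(X, spec) {
  if (!inherits(X, "covariate_matrix")) abort("X must be a covariate_matrix")
  n_assignments <- exp(lgamma(spec$n_subjects + 1) - sum(lgamma(spec$arm_sizes + 1)))
  if (n_assignments > 200000) {
    stopf("%.0f assignments exceed the 200,000 enumeration guard", n_assignments)
  }
  best <- NULL
  assign_rec <- function(arm_of, remaining, arm) {
    if (arm == spec$n_arms) {
      arm_of[remaining] <- arm
      ev <- ds_from_arms(X$basis, arm_of, spec)
      if (is.null(best) || ev$ds_value > best$evaluation$ds_value) {
        best <<- list(arm_of = arm_of, evaluation = ev)
      }
      return(invisible())
    }
    picks <- combn(remaining, spec$arm_sizes[arm])
    for (c in seq_len(ncol(picks))) {
      arm_of2 <- arm_of
      arm_of2[picks[, c]] <- arm
      assign_rec(arm_of2, setdiff(remaining, picks[, c]), arm + 1L)
    }
  }
  assign_rec(integer(spec$n_subjects), seq_len(spec$n_subjects), 1L)
  structure(
    list(
      arm_of = best$arm_of,
      evaluation = best$evaluation,
      n_restarts_run = NA_integer_,
      n_swaps_accepted = NA_integer_,
      seed = NA_integer_,
      spec = spec,
      subject_id = X$subject_id
    ),
    class = "ds_optim"
  )
}

#' @export
print.ds_optim <- function(x, ...) {
  cat(sprintf(
    "<ds_optim> Ds-efficiency %.4f over %s restart(s), %s swap(s) accepted (N = %d, %d arms)\n",
    x$evaluation$ds_efficiency,
    ifelse(is.na(x$n_restarts_run), "exhaustive", x$n_restarts_run),
    ifelse(is.na(x$n_swaps_accepted), "-", x$n_swaps_accepted),
    x$spec$n_subjects, x$spec$n_arms
  ))
  invisible(x)
}

#' Tidy a Ds-optimal allocation into a per-subject tibble
#'
#' @param x A `ds_optim` object.
#' @param ... Unused.
#' @return A tibble with columns `subject_id` and `arm` (arm label).
#' @method tidy ds_optim
#' @export
tidy.ds_optim <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    arm = x$spec$arm_labels[x$arm_of]
  )
}

#' One-row summary of a Ds-optimal allocation
#'
#' @param x A `ds_optim` object.
#' @param ... Unused.
#' @return A tibble with the Ds value, efficiency, restart and swap counts,
#'   and seed.
#' @method glance ds_optim
#' @export
glance.ds_optim <- function(x, ...) {
  tibble::tibble(
    ds_value = x$evaluation$ds_value,
    ds_efficiency = x$evaluation$ds_efficiency,
    n = x$spec$n_subjects,
    t = x$spec$n_arms,
    n_restarts_run = x$n_restarts_run,
    n_swaps_accepted = x$n_swaps_accepted,
    seed = x$seed
  )
}
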