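# Seed scoping: every stochastic entry point takes an optional integer seed.
# A non-NULL seed is applied in a withr scope so the caller's RNG state is
# untouched; NULL means "use the ambient RNG stream".
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Deterministic counter scheme spawning one sub-seed per restart/draw block,
# independent of any parallel execution order. Kept below 2^31 - 1.
spawn_seeds <- function(seed, n) {
  (as.double(seed) + 9973 * seq_len(n)) %% 2147483647
}

# Determinant of a small symmetric positive semi-definite matrix, computed
# from its eigenvalues so that near-zero modes are handled stably.
# Eigenvalues in [-tol, 0] clamp to 0; anything below -tol signals an
# internal error (the residual matrix is PSD by construction).
det_psd <- function(M, tol_scale = 1) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(tol_scale, 1)
  if (any(ev < -tol)) {
    abort("internal error: residual contrast matrix has a negative eigenvalue beyond tolerance")
  }
  ev <- pmax(ev, 0)
  list(det = prod(ev), logdet = sum(log(ev)))
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
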