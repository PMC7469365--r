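# Shared fixtures, all generated in code.

# Replica of the motivating trial structure, encoded, with its 3x54 design.
trial_fixture <- function(seed = 42) {
  replica <- generate_trial_replica(replica_params(seed = seed))
  X <- encode_covariates(
    replica,
    categorical = c("gender", "visit_group"),
    continuous = c("age", "bmi", "score")
  )
  list(replica = replica, X = X, spec = design_spec(c(54, 54, 54)))
}

# Random full-rank instance for criterion-equivalence properties:
# intercept plus p standard-normal columns, near-equal arm sizes.
random_instance <- function(N, p, t) {
  X_raw <- cbind(1, matrix(rnorm(N * p), N, p))
  colnames(X_raw) <- c("(Intercept)", paste0("x", seq_len(p)))
  sizes <- rep(N %/% t, t)
  if (N %% t > 0) sizes[seq_len(N %% t)] <- sizes[seq_len(N %% t)] + 1L
  spec <- design_spec(sizes)
  arm_of <- initial_allocation(spec)
  list(X_raw = X_raw, spec = spec, arm_of = arm_of,
       T_mat = treatment_contrasts(arm_of, spec))
}

# Wrap a plain matrix as the covariate_matrix the package functions expect.
as_covariate_matrix <- function(X_raw) {
  df <- tibble::as_tibble(as.data.frame(X_raw[, -1, drop = FALSE]))
  names(df) <- paste0("x", seq_along(df))
  df$subject_id <- sprintf("S%02d", seq_len(nrow(X_raw)))
  encode_covariates(df, continuous = setdiff(names(df), "subject_id"))
}
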