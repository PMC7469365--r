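test_that("initial allocations realize the arm sizes and repeat under a seed", {
  spec <- design_spec(c(54, 54, 54))
  a <- initial_allocation(spec, seed = 7)
  expect_equal(tabulate(a, 3), c(54, 54, 54))
  expect_identical(a, initial_allocation(spec, seed = 7))
})

test_that("initial allocations are uniform over the 6 permutations of (1,1,1)", {
  spec <- design_spec(c(1, 1, 1))
  draws <- vapply(1:6000, function(s) {
    paste(initial_allocation(spec, seed = s), collapse = "")
  }, character(1))
  counts <- table(draws)
  expect_length(counts, 6)
  # 3-sigma binomial band around 1000
  expect_true(all(abs(counts - 1000) < 3 * sqrt(6000 * (1 / 6) * (5 / 6))))
})

test_that("swap_delta matches recomputation from scratch", {
  withr::with_seed(31, {
    toy <- generate_toy(seed = 12, N = 12, t = 3, n_continuous = 2)
    X <- encode_covariates(toy$table, continuous = c("x1", "x2"))
    arm_of <- initial_allocation(toy$spec, seed = 3)
    state <- optimizer_state(X, arm_of, toy$spec)
    for (rep in 1:30) {
      i <- sample(12, 1)
      j <- sample(which(arm_of != arm_of[i]), 1)
      arm2 <- arm_of
      arm2[c(i, j)] <- arm_of[c(j, i)]
      recompute <- ds_criterion(X, treatment_contrasts(arm2, toy$spec))$ds_value -
        state$current_ds
      expect_equal(swap_delta(state, i, j), recompute,
                   tolerance = 1e-8 * max(abs(recompute), state$current_ds))
    }
  })
})

test_that("swapping identical covariate rows changes nothing", {
  df <- tibble::tibble(subject_id = sprintf("S%d", 1:6),
                       x = c(1, 1, 2, 3, 4, 5))
  X <- encode_covariates(df, continuous = "x")
  spec <- design_spec(c(3, 3))
  state <- optimizer_state(X, c(1L, 2L, 1L, 1L, 2L, 2L), spec)
  expect_equal(swap_delta(state, 1, 2), 0, tolerance = 1e-9)
})

test_that("a swap applied twice returns Ds to its starting value", {
  toy <- generate_toy(seed = 13, N = 9, t = 3)
  X <- encode_covariates(toy$table, continuous = "x1")
  state <- optimizer_state(X, initial_allocation(toy$spec, seed = 1), toy$spec)
  ds0 <- state$current_ds
  i <- which(state$arm_of == 1)[1]
  j <- which(state$arm_of == 2)[1]
  state <- dsalloc:::apply_swap(state, i, j)
  state <- dsalloc:::apply_swap(state, i, j)
  expect_equal(state$current_ds, ds0, tolerance = 1e-9 * ds0)
})

test_that("same-arm swaps are rejected", {
  toy <- generate_toy(seed = 14, N = 6, t = 2)
  X <- encode_covariates(toy$table, continuous = "x1")
  state <- optimizer_state(X, rep(1:2, each = 3), toy$spec)
  expect_error(swap_delta(state, 1, 2), "same arm")
})

test_that("incrementally maintained gram agrees with scratch after a run", {
  toy <- generate_toy(seed = 15, N = 12, t = 3, n_continuous = 2)
  X <- encode_covariates(toy$table, continuous = c("x1", "x2"))
  fit <- exchange_optimize(X, toy$spec, n_restarts = 3, seed = 5)
  scratch <- ds_criterion(X, treatment_contrasts(fit$arm_of, toy$spec))
  expect_equal(fit$evaluation$ds_value, scratch$ds_value,
               tolerance = 1e-8 * max(scratch$ds_value, 1))
})

test_that("intercept-only designs are already optimal: efficiency 1", {
  df <- tibble::tibble(subject_id = sprintf("S%d", 1:9))
  X <- encode_covariates(df)
  fit <- exchange_optimize(X, design_spec(c(3, 3, 3)), n_restarts = 2, seed = 1)
  expect_equal(fit$evaluation$ds_efficiency, 1, tolerance = 1e-10)
})

test_that("exchange search attains the exhaustive optimum on 1..9 line data", {
  df <- tibble::tibble(subject_id = sprintf("S%d", 1:9), x = as.numeric(1:9))
  X <- encode_covariates(df, continuous = "x")
  spec <- design_spec(c(3, 3, 3))
  bf <- brute_force_optimize(X, spec)
  ex <- exchange_optimize(X, spec, n_restarts = 20, seed = 2)
  expect_equal(ex$evaluation$ds_value, bf$evaluation$ds_value,
               tolerance = 1e-8 * bf$evaluation$ds_value)
})

test_that("exhaustive search on a flat landscape scores N^(t-1) everywhere", {
  df <- tibble::tibble(subject_id = sprintf("S%d", 1:4))
  X <- encode_covariates(df)
  bf <- brute_force_optimize(X, design_spec(c(2, 2)))
  expect_equal(bf$evaluation$ds_value, 4, tolerance = 1e-10)
})

test_that("the exhaustive 3/3 optimum balances the covariate sums", {
  df <- tibble::tibble(subject_id = sprintf("S%d", 1:6), x = as.numeric(1:6))
  X <- encode_covariates(df, continuous = "x")
  bf <- brute_force_optimize(X, design_spec(c(3, 3)))
  sums <- tapply(df$x, bf$arm_of, sum)
  expect_lte(abs(diff(sums)), 1)  # 21 splits as 10/11 at best
})

test_that("the enumeration guard rejects oversized problems with the count", {
  df <- tibble::tibble(subject_id = sprintf("S%03d", 1:30), x = rnorm(30))
  X <- encode_covariates(df, continuous = "x")
  expect_error(brute_force_optimize(X, design_spec(c(10, 10, 10))), "guard")
})

test_that("exchange with 20 restarts matches brute force on 25 random instances", {
  withr::with_seed(32, {
    for (rep in 1:25) {
      N <- sample(6:10, 1)
      t <- sample(2:3, 1)
      toy <- generate_toy(seed = sample.int(1e6, 1), N = N, t = t,
                         n_continuous = sample(1:2, 1))
      X <- encode_covariates(toy$table,
                             continuous = grep("^x", names(toy$table), value = TRUE))
      bf <- brute_force_optimize(X, toy$spec)
      ex <- exchange_optimize(X, toy$spec, n_restarts = 20, seed = rep)
      expect_equal(ex$evaluation$ds_value, bf$evaluation$ds_value,
                   tolerance = 1e-8 * max(bf$evaluation$ds_value, 1))
    }
  })
})

test_that("the optimizer dominates 1000 complete-random allocations", {
  withr::with_seed(33, {
    for (rep in 1:3) {
      toy <- generate_toy(seed = rep, N = 15, t = 3, n_continuous = 2)
      X <- encode_covariates(toy$table, continuous = c("x1", "x2"))
      ex <- exchange_optimize(X, toy$spec, n_restarts = 10, seed = rep)
      mc <- monte_carlo(X, toy$spec, "complete", n_draws = 1000, seed = rep)
      expect_gte(ex$evaluation$ds_efficiency, mc$maximum)
    }
  })
})

test_that("different seeds give different allocations of near-equal efficiency", {
  fx <- trial_fixture()
  f1 <- exchange_optimize(fx$X, fx$spec, n_restarts = 10, seed = 1)
  f2 <- exchange_optimize(fx$X, fx$spec, n_restarts = 10, seed = 2)
  expect_gte(sum(f1$arm_of != f2$arm_of), 1)
  expect_lt(abs(f1$evaluation$ds_efficiency - f2$evaluation$ds_efficiency), 0.002)
})
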