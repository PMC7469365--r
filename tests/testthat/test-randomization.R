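test_that("complete randomization keeps the arm sizes and repeats under a seed", {
  spec <- design_spec(c(54, 54, 54))
  a <- complete_randomization(spec, seed = 3)
  expect_equal(tabulate(a, 3), c(54, 54, 54))
  expect_identical(a, complete_randomization(spec, seed = 3))
})

test_that("two-subject randomization is a fair coin over 2000 seeds", {
  spec <- design_spec(c(1, 1))
  firsts <- vapply(1:2000, function(s) complete_randomization(spec, seed = s)[1],
                   integer(1))
  n1 <- sum(firsts == 1L)
  expect_lt(abs(n1 - 1000), 3 * sqrt(2000 * 0.25))
})

test_that("stratified draws hit every prescribed stratum-by-arm cell exactly", {
  fx <- trial_fixture()
  counts <- even_stratum_counts(fx$replica$visit_group, fx$spec)
  expect_true(all(abs(sweep(counts, 1, rowMeans(counts))) <= 1))
  expect_equal(colSums(counts), c(A = 54, B = 54, C = 54))
  spec <- design_spec(c(54, 54, 54), stratum_arm_counts = counts)
  for (s in 1:5) {
    a <- stratified_randomization(spec, fx$replica$visit_group, seed = s)
    realized <- table(fx$replica$visit_group, a)
    expect_equal(unclass(realized)[rownames(counts), ], unclass(counts),
                 ignore_attr = TRUE)
  }
})

test_that("a single all-covering stratum behaves like complete randomization", {
  strata <- rep("all", 6)
  spec0 <- design_spec(c(3, 3))
  spec <- design_spec(c(3, 3), stratum_arm_counts = even_stratum_counts(strata, spec0))
  a <- stratified_randomization(spec, strata, seed = 5)
  expect_equal(tabulate(a, 2), c(3, 3))
  # same seed, same uniform shuffle mechanism as the complete generator
  expect_identical(a, complete_randomization(spec0, seed = 5))
})

test_that("two strata of sizes 4 and 2 enumerate to exactly 12 outcomes", {
  strata <- rep(c("g1", "g2"), c(4, 2))
  counts <- matrix(c(2, 1, 2, 1), nrow = 2, dimnames = list(c("g1", "g2"), NULL))
  spec <- design_spec(c(3, 3), stratum_arm_counts = counts)
  seen <- unique(vapply(1:600, function(s) {
    paste(stratified_randomization(spec, strata, seed = s), collapse = "")
  }, character(1)))
  expect_length(seen, 6 * 2)
})

test_that("inconsistent stratum counts are rejected naming the stratum", {
  strata <- rep(c("g1", "g2"), c(4, 2))
  counts <- matrix(c(1, 2, 1, 2), nrow = 2, dimnames = list(c("g1", "g2"), NULL))
  spec <- design_spec(c(3, 3), stratum_arm_counts = counts)
  expect_error(stratified_randomization(spec, strata, seed = 1), "g1")
})

test_that("monte_carlo on an intercept-only design is identically 1", {
  df <- tibble::tibble(subject_id = sprintf("S%d", 1:9))
  X <- encode_covariates(df)
  mc <- monte_carlo(X, design_spec(c(3, 3, 3)), n_draws = 100, seed = 1)
  expect_equal(unname(mc$interval_95), c(1, 1), tolerance = 1e-12)
  expect_equal(mc$maximum, 1, tolerance = 1e-12)
})

test_that("summary invariants hold and the interval covers ~95% of draws", {
  toy <- generate_toy(seed = 41, N = 12, t = 3, n_continuous = 2)
  X <- encode_covariates(toy$table, continuous = c("x1", "x2"))
  mc <- monte_carlo(X, toy$spec, "complete", n_draws = 400, seed = 2)
  expect_lte(mc$interval_95["lower"], mc$interval_95["upper"])
  expect_lte(mc$interval_95["upper"], mc$maximum)
  expect_lte(mc$minimum, mc$interval_95["lower"])
  expect_lte(mc$maximum, 1 + 1e-10)
  inside <- sum(mc$efficiencies >= mc$interval_95["lower"] &
                mc$efficiencies <= mc$interval_95["upper"])
  expect_gte(inside, 0.95 * 400 - 2)
})

test_that("identical seeds reproduce the efficiencies vector bitwise", {
  toy <- generate_toy(seed = 42, N = 12, t = 3)
  X <- encode_covariates(toy$table, continuous = "x1")
  m1 <- monte_carlo(X, toy$spec, "complete", n_draws = 150, seed = 9)
  m2 <- monte_carlo(X, toy$spec, "complete", n_draws = 150, seed = 9)
  expect_identical(m1$efficiencies, m2$efficiencies)
})

test_that("stratified randomization stochastically dominates complete", {
  fx <- trial_fixture()
  counts <- even_stratum_counts(fx$replica$visit_group, fx$spec)
  spec_s <- design_spec(c(54, 54, 54), stratum_arm_counts = counts)
  mc_c <- monte_carlo(fx$X, fx$spec, "complete", n_draws = 1000, seed = 5)
  mc_s <- monte_carlo(fx$X, spec_s, "stratified", strata = fx$replica$visit_group,
                      n_draws = 1000, seed = 5)
  qs <- c(0.025, 0.5, 0.975)
  expect_true(all(quantile(mc_s$efficiencies, qs) > quantile(mc_c$efficiencies, qs)))
})

test_that("the efficiencies vector round-trips through CSV", {
  toy <- generate_toy(seed = 43, N = 10, t = 2)
  X <- encode_covariates(toy$table, continuous = "x1")
  mc <- monte_carlo(X, toy$spec, "complete", n_draws = 120, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_efficiencies(mc, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), "ds_efficiency")
  expect_equal(back$ds_efficiency, mc$efficiencies, tolerance = 1e-12)
})
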