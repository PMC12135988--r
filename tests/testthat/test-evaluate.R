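# Accuracy metrics, benchmark conditions, bootstrap intervals.

test_that("RMS deviation from truth uses the n_rep denominator", {
  expect_equal(rms_deviation(c(10, 10, 10), 10), 0)
  expect_equal(rms_deviation(10.5, 10), 0.5)   # single replicate
  expect_equal(rms_deviation(c(9, 11), 10), 1) # not the sample sd
  vals <- matrix(c(9, 11, 28, 32), 2, 2)
  expect_equal(rms_deviation(vals, c(10, 30)), c(1, 2))
  expect_error(rms_deviation(matrix(numeric(0), 0, 1), 10), "replicate")
})

test_that("average relative deviation in percent", {
  expect_equal(avg_rel_deviation(c(0, 0), c(10, 30)), 0)
  expect_equal(avg_rel_deviation(c(1.7, 1.5, 2.0, 3.5),
                                 c(10, 30, 50, 70)),
               mean(c(17, 5, 4, 5)))
  expect_error(avg_rel_deviation(1, 0), "zero")
})

test_that("bootstrap interval degenerates and shrinks correctly", {
  same <- matrix(10.5, 50, 1)
  ci <- bootstrap_ci(same, 10)
  expect_equal(ci[1], ci[2])
  set.seed(1)
  vals <- matrix(rnorm(4000, 10, 1), ncol = 1)
  w_small <- diff(bootstrap_ci(vals[1:1000, , drop = FALSE], 10,
                               n_boot = 400))
  w_big <- diff(bootstrap_ci(vals, 10, n_boot = 400))
  # quadrupling n_rep halves the width, within tolerance
  expect_lt(abs(w_small / w_big - 2), 0.5)
})

test_that("conditions are assembled with the benchmark settings", {
  cond <- cond_coreshell()
  expect_equal(cond$roles, c("saxs", "sans"))
  expect_equal(vapply(cond$datasets, `[[`, numeric(1), "M"), c(400, 50))
  expect_equal(cond$datasets[[1]]$noise$s, 100)
  expect_equal(cond$datasets[[1]]$noise$c, 0.85)
  expect_equal(cond$datasets[[2]]$noise$s, 10)
  expect_equal(cond$datasets[[2]]$noise$c, 0.95)
  expect_equal(cond$truth[["a.1"]], 0.5)
  expect_equal(cond$truth[["b.2"]], 1e-4)
  cond3 <- cond_coreshell(M_core = 50)
  expect_equal(cond3$roles, c("saxs", "sans", "core"))
  expect_equal(cond3$truth[["rho1.3"]], 0)
})

test_that("replicated runs recover truth without noise, deterministically", {
  cond <- cond_coreshell(M_saxs = 120, M_sans = 40,
                         noise_factor = 1e-16)
  ev <- run_condition(cond, modes = "naive", n_rep = 2, seed = 4)
  expect_lt(ev$results$naive$avg_rel, 0.1)
  ev2 <- run_condition(cond, modes = "naive", n_rep = 2, seed = 4)
  expect_identical(ev$results$naive$values, ev2$results$naive$values)
})

test_that("single-dataset modes and sweep outputs have the right shape", {
  cond <- cond_coreshell(M_saxs = 100, M_sans = 40)
  ev <- run_condition(cond, modes = c("naive", "sans"), n_rep = 3,
                      seed = 8)
  expect_named(ev$results, c("naive", "sans"))
  expect_equal(dim(ev$results$sans$values), c(3, 4))
  expect_error(run_condition(cond, modes = "core", n_rep = 1),
               "unknown mode")
  sw <- misscale_sweep(factors = c(1, 4), n_rep = 2, seed = 8,
                       M_saxs = 100, M_sans = 40)
  expect_equal(sw$factor, c(1, 4))
  expect_true(all(c("R_c", "R_2", "avg_rel") %in% names(sw)))
})
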