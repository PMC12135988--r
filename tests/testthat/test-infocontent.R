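# Hessians, number of good parameters, Shannon channels, DOF partition.

test_that("forward-difference Hessian: quadratic oracle and symmetry", {
  A <- matrix(c(4, 1, 0.5, 1, 3, -0.2, 0.5, -0.2, 2), 3, 3)
  f <- function(x) as.numeric(t(x) %*% A %*% x)
  H <- numeric_hessian(f, c(1, -2, 0.5))
  expect_lt(max(abs(H - 2 * A) / max(abs(A))), 1e-4)
  expect_identical(H, t(H))
  # step halving changes entries only marginally (self-convergence)
  H2 <- numeric_hessian(f, c(1, -2, 0.5), rel_step = 5e-5)
  expect_lt(max(abs(H2 - H)) / max(abs(H)), 1e-3)
  # central-difference cross-check on a non-quadratic objective
  g <- function(x) sum(exp(x / 3)) + x[1]^2 * x[2]
  x0 <- c(0.7, -0.4)
  Hf <- numeric_hessian(g, x0)
  h <- 1e-4
  Hc <- matrix(0, 2, 2)
  for (k in 1:2) for (l in 1:2) {
    pp <- x0; pp[k] <- pp[k] + h; pp[l] <- pp[l] + h
    pm <- x0; pm[k] <- pm[k] + h; pm[l] <- pm[l] - h
    mp <- x0; mp[k] <- mp[k] - h; mp[l] <- mp[l] + h
    mm <- x0; mm[k] <- mm[k] - h; mm[l] <- mm[l] - h
    Hc[k, l] <- (g(pp) - g(pm) - g(mp) + g(mm)) / (4 * h^2)
  }
  expect_lt(max(abs(Hf - Hc)) / max(abs(Hc)), 1e-2)
  expect_error(numeric_hessian(function(x) NaN, c(1, 2)), "finite")
})

test_that("number of good parameters from the normalized eigenspectrum", {
  # K = 2 diagonal toy: lambda = (10, 0.1), alpha = 1
  H <- diag(c(10, 0.1)) * 2   # B = H/2 after unit prior widths
  expect_equal(ng_from_hessian(H, c(1, 1), alpha = 1),
               10 / 11 + 0.1 / 1.1, tolerance = 1e-12)
  # limits
  expect_equal(ng_from_hessian(H, c(1, 1), alpha = 1e-14), 2,
               tolerance = 1e-9)
  expect_lt(ng_from_hessian(H, c(1, 1), alpha = 1e14), 1e-9)
  expect_warning(ng_from_hessian(diag(c(1, -0.1)), c(1, 1), 1), "saddle")
})

test_that("Shannon channels", {
  expect_equal(shannon_channels(0.1, 0.1 + pi / 140, 140), 1)
  expect_equal(shannon_channels(0.001, 0.5, 140), 0.499 * 140 / pi)
  expect_equal(shannon_channels(0.001, 0.5, 280),
               2 * shannon_channels(0.001, 0.5, 140))
  expect_error(shannon_channels(0.5, 0.1, 100), "qmin")
})

test_that("DOF partition sums exactly and yields per-dataset reduced chi2", {
  # equal stand-alone counts split the total evenly
  eq <- dof_partition(c(5, 5), N_g = 8, M = c(100, 100))
  expect_equal(eq$N_g, c(4, 4))
  # worked example: n_g = (8, 4), N_g = 9 -> (6, 3)
  dt <- dof_partition(c(8, 4), N_g = 9, M = c(400, 50),
                      chi2 = c(394, 47))
  expect_equal(dt$N_g, c(6, 3))
  expect_equal(sum(dt$N_g), 9)
  expect_equal(dt$dof, c(394, 47))
  expect_equal(dt$chi2_reduced, c(394 / 394, 47 / 47))
  expect_equal(attr(dt, "dof_total"), 450 - 9)
  expect_error(dof_partition(c(8, 4), 9, M = c(400, 3)), "degenerate")
  expect_error(dof_partition(c(2, 2), 9, M = c(50, 50)), "exceed")
})
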