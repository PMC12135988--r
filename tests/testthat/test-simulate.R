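# Synthetic data generation: grids, empirical errors, sampling,
# mis-scaling, resolution columns.

test_that("uniform q grids", {
  expect_equal(make_qgrid(0.001, 0.5, 3), c(0.001, 0.2505, 0.5))
  g <- make_qgrid(0.001, 0.5, 400)
  expect_equal(diff(g), rep((0.5 - 0.001) / 399, 399))
  g2 <- make_qgrid(0.0001, 0.3, 50)
  expect_equal(range(g2), c(0.0001, 0.3))
  expect_length(g2, 50)
  expect_error(make_qgrid(0.001, 0.5, 1), "M")
  expect_error(make_qgrid(0.5, 0.001, 10), "qmin")
})

test_that("empirical error model: scaling properties", {
  q <- make_qgrid(1e-3, 0.5, 200)
  I <- coreshell_intensity(q, c(10, 30, 50, 70), c(2, 3, 4), a = 0.5,
                           b = 1e-5)
  s1 <- sedlak_sigma(q, I, noise_spec("saxs"))
  expect_true(all(s1 > 0))
  # noise factor multiplies the variance: factor 4 doubles sigma
  s4 <- sedlak_sigma(q, I, noise_spec("saxs", noise_factor = 4))
  expect_equal(s4, 2 * s1, tolerance = 1e-12)
  # larger absolute scale s -> smaller relative errors at every q
  lo <- sedlak_sigma(q, I, noise_spec("custom", s = 10, c_buffer = 0.85))
  hi <- sedlak_sigma(q, I, noise_spec("custom", s = 100, c_buffer = 0.85))
  expect_true(all(hi / I < lo / I))
  # the SAXS preset has a higher signal-to-noise ratio than SANS
  sx <- sedlak_sigma(q, I, noise_spec("saxs"))
  sn <- sedlak_sigma(q, I, noise_spec("sans"))
  expect_true(all(I / sx > I / sn))
  expect_error(sedlak_sigma(c(0, q[-1]), I, noise_spec("saxs")),
               "positive")
})

test_that("sampling: normality, determinism, zero-noise limit", {
  q <- make_qgrid(1e-3, 0.5, 10000)
  I <- rep(1, 10000)
  sig <- rep(0.1, 10000)
  crv <- sample_curve(q, I, sig, seed = 99)
  z <- (crv$I - I) / sig
  expect_lt(abs(mean(z)), 0.03)
  expect_gt(sd(z), 0.97); expect_lt(sd(z), 1.03)
  # same seed -> identical draw
  crv2 <- sample_curve(q, I, sig, seed = 99)
  expect_identical(crv$I, crv2$I)
  # vanishing noise factor: simulated curve collapses onto the model
  m <- sas_model("coreshell3"); th <- truth_coreshell()
  qq <- make_qgrid(1e-3, 0.5, 50)
  crv3 <- simulate_dataset(m, th, 1, qq,
                           noise_spec("saxs", noise_factor = 1e-20),
                           seed = 1)
  expect_equal(crv3$I, corefit:::model_intensity(m, qq, th, 1),
               tolerance = 1e-8)
})

test_that("error mis-scaling decouples reported errors from fluctuations", {
  q <- make_qgrid(1e-3, 0.5, 5000)
  crv <- sample_curve(q, rep(1, 5000), rep(0.2, 5000), seed = 5)
  expect_equal(misscale_errors(crv, 1), crv)
  m2 <- misscale_errors(crv, 2)
  expect_equal(m2$I, crv$I)           # intensities untouched
  expect_equal(m2$sigma, 2 * crv$sigma)
  z2 <- (m2$I - 1) / m2$sigma
  expect_equal(mean(z2^2), 0.25, tolerance = 0.05)
  expect_error(misscale_errors(crv, 0), "> 0")
})

test_that("synthetic resolution column", {
  q <- make_qgrid(1e-3, 0.5, 100)
  s1 <- synth_sigma_q(q)
  expect_true(all(s1 > 0))
  expect_equal(synth_sigma_q(q, multiplier = 2), 2 * s1)
  expect_equal(synth_sigma_q(q, multiplier = 3), 3 * s1)
  expect_error(synth_sigma_q(q, relative_resolution = -1), ">= 0")
})

test_that("simulate_dataset: reproducibility, smearing, misscale wiring", {
  m <- sas_model("coreshell3"); th <- truth_coreshell()
  q <- make_qgrid(1e-3, 0.5, 60)
  a1 <- simulate_dataset(m, th, 2, q, noise_spec("sans"), seed = 4)
  a2 <- simulate_dataset(m, th, 2, q, noise_spec("sans"), seed = 4)
  expect_identical(a1$I, a2$I)
  # resolution widths are used for the model and attached to the curve
  sq <- synth_sigma_q(q)
  sm <- simulate_dataset(m, th, 2, q, noise_spec("sans"), sigma_q = sq,
                         seed = 4, sample = FALSE)
  expect_equal(sm$sigma_q, sq)
  un <- simulate_dataset(m, th, 2, q, noise_spec("sans"), seed = 4,
                         sample = FALSE)
  expect_false(isTRUE(all.equal(sm$I, un$I)))  # smearing changed the curve
  # reported errors carry the mis-scaling factor from the noise spec
  ms <- simulate_dataset(m, th, 2, q, noise_spec("sans", misscale = 10),
                         seed = 4)
  base <- simulate_dataset(m, th, 2, q, noise_spec("sans"), seed = 4)
  expect_equal(ms$sigma, 10 * base$sigma)
  expect_identical(ms$I, base$I)
})
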