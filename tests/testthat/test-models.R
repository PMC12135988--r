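# Analytic form factors, structure factor, mixture and smearing.

test_that("sphere amplitude: limits, closed-form values, first zero", {
  expect_equal(sphere_amplitude(0, 50), 1)
  expect_equal(sphere_amplitude(1e-9, 5), 1, tolerance = 1e-12)
  # qR = pi: sin(pi) = 0, cos(pi) = -1 -> 3/pi^2
  expect_equal(sphere_amplitude(pi / 50, 50), 3 / pi^2, tolerance = 1e-12)
  # first zero of the closed form, located by bracketed root finding
  root <- uniroot(function(x) 3 * (sin(x) - x * cos(x)) / x^3,
                  c(3, 5), tol = 1e-10)$root
  expect_equal(root, 4.4934, tolerance = 1e-4)
  expect_equal(sphere_amplitude(root / 20, 20), 0, tolerance = 1e-10)
  expect_error(sphere_amplitude(0.1, -1), "positive")
})

test_that("core-multishell reduces to a homogeneous sphere and to a + b", {
  q <- make_qgrid(1e-3, 0.5, 200)
  radii <- c(10, 30, 50, 70)
  I_cs <- coreshell_intensity(q, radii, rho = c(1, 1, 1), a = 2, b = 0.1)
  I_sph <- 2 * sphere_amplitude(q, 70)^2 + 0.1
  expect_lt(max(abs(I_cs / I_sph - 1)), 1e-10)
  # q -> 0 limit is a + b
  expect_equal(coreshell_intensity(1e-9, radii, c(2, 3, 4), a = 0.5,
                                   b = 1e-5), 0.5 + 1e-5,
               tolerance = 1e-9)
  expect_error(coreshell_intensity(q, c(10, 5, 50, 70), c(1, 1, 1)),
               "increasing")
})

test_that("form factor depends on contrasts only through their ratios", {
  q <- make_qgrid(1e-3, 0.5, 100)
  radii <- c(10, 30, 50, 70)
  # multiplying all contrasts (incl. the core reference) by a common
  # constant is absorbed by the normalization
  I1 <- coreshell_intensity(q, radii, rho = c(-0.1, 0.1, 0.05))
  amp <- corefit:::.coreshell_amp(q, radii, 7 * c(1, -0.1, 0.1, 0.05))
  I2 <- (amp$A / amp$A0)^2
  expect_lt(max(abs(I1 - I2)), 1e-12)
})

test_that("core-multishell matches the Debye point-cloud oracle", {
  set.seed(42)
  radii <- c(10, 30, 50, 70)
  rho_all <- c(1, 2, 3, 4)
  cloud <- coreshell_cloud(4000, radii, rho_all)
  # Monte-Carlo comparison where the cloud is informative (P above the
  # sampling noise floor of a few-thousand-point cloud)
  q <- make_qgrid(5e-3, 0.15, 12)
  P_mc <- debye_pointcloud(cloud$xyz, cloud$w, q)
  P <- coreshell_intensity(q, radii, rho_all[-1])
  keep <- P > 2e-2
  expect_gt(sum(keep), 3)
  expect_lt(max(abs(P - P_mc)[keep] / P[keep]), 0.01)
  # radial-quadrature oracle over the full range: A(q) = 4 pi
  # int rho(r) r^2 sinc(qr) dr for the spherically symmetric profile
  r <- seq(1e-4, 70, length.out = 60000)
  rho_r <- rho_all[pmin(findInterval(r, radii) + 1L, length(rho_all))]
  qf <- make_qgrid(1e-3, 0.5, 60)
  A <- vapply(qf, function(qq)
    sum(rho_r * r^2 * sin(qq * r) / (qq * r)) , numeric(1))
  P_quad <- (A / sum(rho_r * r^2))^2
  P_full <- coreshell_intensity(qf, radii, rho_all[-1])
  expect_lt(max(abs(P_full - P_quad)), 1e-5)
})

test_that("cylinder amplitude: limits and orientational average oracle", {
  expect_equal(cylinder_amplitude(1e-12, 20, 100, 0.7), 1,
               tolerance = 1e-9)
  # beta = 0: radial term is 1, amplitude is the axial sinc
  y <- 0.05 * 100 / 2
  expect_equal(cylinder_amplitude(0.05, 20, 100, 0), sin(y) / y,
               tolerance = 1e-10)
  expect_error(cylinder_amplitude(0.1, -3, 10, 0), "> 0")
  # orientationally averaged single cylinder vs point cloud
  set.seed(7)
  xyz <- sample_cylinder(4000, 25, 120)
  q <- make_qgrid(2e-3, 0.1, 10)
  P_mc <- debye_pointcloud(xyz, rep(1, nrow(xyz)), q)
  P <- stacked_cylinder_intensity(q, R = 25, L = 120, rho = 1)
  keep <- P > 2e-2
  expect_gt(sum(keep), 3)
  expect_lt(max(abs(P - P_mc)[keep] / P[keep]), 0.01)
})

test_that("stacked cylinders: reductions and quadrature convergence", {
  q <- make_qgrid(1e-3, 0.3, 80)
  # equal contrasts, contiguous stack == one cylinder of the total length
  I_stack <- stacked_cylinder_intensity(q, R = 30, L = c(40, 100, 60),
                                        rho = c(1, 1, 1), a = 0.7, b = 0)
  I_single <- stacked_cylinder_intensity(q, R = 30, L = 200, rho = 1,
                                         a = 0.7, b = 0)
  expect_lt(max(abs(I_stack / I_single - 1)), 1e-8)
  # doubling the number of beta nodes barely changes the curve
  I_256 <- stacked_cylinder_intensity(q, R = 30, L = c(40, 100, 60),
                                      rho = c(1, -0.5, 0.25),
                                      n_nodes = 256)
  I_128 <- stacked_cylinder_intensity(q, R = 30, L = c(40, 100, 60),
                                      rho = c(1, -0.5, 0.25))
  expect_lt(max(abs(I_256 / I_128 - 1)), 1e-6)
  expect_error(stacked_cylinder_intensity(q, R = 30, L = numeric(0)),
               "at least one")
  expect_error(stacked_cylinder_intensity(q, R = -1, L = 10), "> 0")
})

test_that("Percus-Yevick hard-sphere structure factor", {
  q <- make_qgrid(1e-3, 0.5, 200)
  expect_equal(hardsphere_sq(q, 70, 0), rep(1, 200))
  S <- hardsphere_sq(q, 70, 0.2)
  # compressibility limit at q -> 0
  expect_equal(hardsphere_sq(1e-5, 70, 0.2)[1],
               (1 - 0.2)^4 / (1 + 2 * 0.2)^2, tolerance = 1e-9)
  # -> 1 at large q
  expect_lt(abs(hardsphere_sq(50, 70, 0.2) - 1), 1e-2)
  expect_error(hardsphere_sq(q, 70, 0.8), "eta")
  expect_error(hardsphere_sq(q, -1, 0.2), "R_hs")
})

test_that("mixture model: limits and grid checks", {
  q <- make_qgrid(1e-3, 0.3, 50)
  I1 <- exp(-q * 10); I2 <- exp(-q * 40)
  expect_equal(mixture_intensity(q, I1, I2, f1 = 1, s = 2), 2 * I1)
  expect_equal(mixture_intensity(q, I1, I2, f1 = 0, s = 1), I2)
  half <- mixture_intensity(q, I1, I2, f1 = 0.5)
  expect_equal(half, (I1 + I2) / 2)
  expect_error(mixture_intensity(q, I1[-1], I2, 0.5), "same q grid")
  expect_error(mixture_intensity(q, I1, I2, f1 = 1.2), "f1")
})

test_that("Gaussian smearing: conservation, identity, linearity, minima", {
  q <- make_qgrid(5e-3, 0.4, 120)
  sig_q <- synth_sigma_q(q)
  # a flat curve is conserved exactly by the renormalized kernel
  expect_equal(smear_model(q, function(qq) rep(3.5, length(qq)), sig_q),
               rep(3.5, 120), tolerance = 1e-12)
  # zero width is the identity
  f <- function(qq) sphere_amplitude(qq, 50)^2
  expect_equal(smear_model(q, f, rep(0, 120)), f(q))
  # linear in the model
  g <- function(qq) exp(-qq * 5)
  sm <- smear_model(q, function(qq) 2 * f(qq) + 3 * g(qq), sig_q)
  expect_equal(sm, 2 * smear_model(q, f, sig_q) +
                 3 * smear_model(q, g, sig_q), tolerance = 1e-12)
  # smearing fills in the sharp sphere minimum
  qmin1 <- 4.4934 / 50
  expect_gt(smear_model(qmin1, f, 0.02 * qmin1 * 5), f(qmin1))
})

test_that("model registry: layout, evaluation, hard-sphere composition", {
  m <- sas_model("coreshell3")
  expect_equal(model_par_names(m, 2),
               c("R_c", "R_1", "R_2", "R_3",
                 paste0(c("rho1", "rho2", "rho3", "a", "b"), ".1"),
                 paste0(c("rho1", "rho2", "rho3", "a", "b"), ".2")))
  th <- truth_coreshell()
  q <- make_qgrid(1e-3, 0.5, 50)
  expect_equal(corefit:::model_intensity(m, q, th, 1),
               coreshell_intensity(q, th[1:4], th[5:7], th["a.1"],
                                   th["b.1"]))
  mhs <- sas_model("coreshell3", hs_eta = 0.2)
  Ihs <- corefit:::model_intensity(mhs, q, th, 1)
  sq <- hardsphere_sq(q, th[["R_3"]], 0.2)
  expect_equal(Ihs, (coreshell_intensity(q, th[1:4], th[5:7]) *
                       th[["a.1"]] - 0) * sq + th[["b.1"]],
               tolerance = 1e-12)
  expect_true(all(c("coreshell3", "stackedcyl3", "mixture") %in%
                    list_models()))
})
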