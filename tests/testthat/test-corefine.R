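# The co-refinement engine: objective pieces, weighting schemes, the
# Gaussian-linear conjugate oracle, the alpha scan, and the fitted-object
# methods.

make_line_model <- function() {
  sas_model("custom", shared = c("b0", "b1"),
            fn = function(q, sh, ds, j) sh[["b0"]] + sh[["b1"]] * q)
}

line_data <- function(n = 40, sigma = 0.5, beta = c(2, 3), seed = 1) {
  set.seed(seed)
  q <- seq(0.1, 4, length.out = n)
  sas_curve(q, beta[1] + beta[2] * q + rnorm(n, 0, sigma),
            rep(sigma, n), label = "line")
}

test_that("chi-square and prior penalty arithmetic", {
  crv <- sas_curve(1:3, c(1, 2, 3), c(1, 1, 1))
  expect_equal(chi2(crv, c(1, 2, 3)), 0)
  expect_equal(chi2(crv, c(0, 0, 0)), 14)  # residuals 1, 2, 3
  crv2 <- sas_curve(1:5, rep(1, 5), rep(0.5, 5))
  expect_equal(chi2(crv2, rep(0.5, 5)), 5) # all residuals exactly 1 sigma
  pri <- prior_set(c("x", "y", "z"), kind = c("gaussian", "uniform",
                                              "gaussian"),
                   mu = c(1, 5, -2), sigma = c(2, 1, 0.5))
  expect_equal(prior_penalty(c(x = 1, y = 9, z = -2), pri), 0)
  expect_equal(prior_penalty(c(x = 5, y = 0, z = -2), pri), 4)
  # brute-force cross-check over the gaussian subset only
  x <- c(x = 2.2, y = 7, z = -1.1)
  expect_equal(prior_penalty(x, pri),
               ((2.2 - 1) / 2)^2 + ((-1.1 + 2) / 0.5)^2)
})

test_that("weighting schemes and their error-scaling realization", {
  curves <- list(sas_curve(1:50 / 100, rnorm(50, 10), rep(1, 50)),
                 sas_curve(1:400 / 800, rnorm(400, 10), rep(1, 400)))
  expect_equal(scheme_weights(curves, "naive"), c(1, 1))
  expect_equal(scheme_weights(curves, "reduced"), c(1 / 50, 1 / 400))
  expect_equal(scheme_weights(curves, "information", ng_bift = c(8, 12)),
               c(8 / 50, 12 / 400))
  expect_error(scheme_weights(curves, "information", ng_bift = 5),
               "per dataset")
})

test_that("minimizer is invariant to a common factor on the weights", {
  sim <- sim_pair(seed = 21)
  pri <- load_priors("Uniform_5s")
  f1 <- corefit(sim$curves, sim$model, pri, weights = c(1, 1))
  f2 <- corefit(sim$curves, sim$model, pri, weights = c(7, 7))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-3)
})

test_that("naive and reduced schemes coincide for equal dataset sizes", {
  sim <- sim_pair(seed = 22, M_saxs = 120, M_sans = 120)
  pri <- load_priors("Uniform_5s")
  fn <- corefit(sim$curves, sim$model, pri, scheme = "naive")
  fr <- corefit(sim$curves, sim$model, pri, scheme = "reduced")
  expect_equal(coef(fn), coef(fr), tolerance = 1e-3)
})

test_that("zero-noise co-refinement recovers the truth exactly", {
  m <- sas_model("coreshell3"); th <- truth_coreshell()
  curves <- list(
    simulate_dataset(m, th, 1, make_qgrid(1e-3, 0.5, 400),
                     noise_spec("saxs"), sample = FALSE),
    simulate_dataset(m, th, 2, make_qgrid(1e-3, 0.5, 50),
                     noise_spec("sans"), sample = FALSE))
  for (sch in c("naive", "reduced")) {
    fit <- corefit(curves, m, load_priors("Uniform_5s"), scheme = sch)
    expect_lt(max(abs(coef(fit)[1:4] / th[1:4] - 1)), 1e-3)
  }
})

test_that("penalized fit matches the conjugate Gaussian-linear solution", {
  crv <- line_data()
  model <- make_line_model()
  pri <- prior_set(c("b0", "b1"), "gaussian", mu = c(1, 2),
                   sigma = c(1, 0.5))
  X <- cbind(1, crv$q)
  W <- diag(1 / crv$sigma^2)
  Sig_inv <- diag(1 / pri$sigma^2)
  for (alpha in c(0.1, 1, 10)) {
    fit <- corefit(crv, model, pri, alpha = alpha)
    closed <- solve(t(X) %*% W %*% X + alpha * Sig_inv,
                    t(X) %*% W %*% crv$I + alpha * Sig_inv %*% pri$mu)
    expect_lt(max(abs(coef(fit) - closed)), 1e-8)
  }
})

test_that("evidence reproduces the closed-form marginal likelihood shape", {
  crv <- line_data(seed = 3)
  model <- make_line_model()
  pri <- prior_set(c("b0", "b1"), "gaussian", mu = c(0, 0),
                   sigma = c(2, 2))
  alphas <- 10^seq(-2, 2, length.out = 11)
  # closed form: y ~ N(X mu, W^-1 + X Sigma X' / alpha)
  X <- cbind(1, crv$q)
  logml <- vapply(alphas, function(a) {
    V <- diag(crv$sigma^2) + X %*% diag(pri$sigma^2) %*% t(X) / a
    r <- crv$I - as.numeric(X %*% pri$mu)
    -0.5 * (sum(r * solve(V, r)) + determinant(V)$modulus)
  }, numeric(1))
  env <- corefit:::.fit_env(list(crv), model, pri, 1)
  logp <- vapply(alphas, function(a) {
    f <- corefit:::.fit_at_alpha(env, a)
    corefit:::.log_evidence(f, env$priors, a)
  }, numeric(1))
  expect_equal(which.max(logp), which.max(logml))
  # same shape up to an additive constant
  d1 <- logp - max(logp); d2 <- logml - max(logml)
  expect_lt(max(abs(d1 - d2)), 0.05)
})

test_that("large alpha pulls the refined parameters onto the prior mean", {
  crv <- line_data(seed = 9)
  model <- make_line_model()
  pri <- prior_set(c("b0", "b1"), "gaussian", mu = c(0.5, 1),
                   sigma = c(1, 1))
  fit <- corefit(crv, model, pri, alpha = 1e8)
  expect_equal(unname(coef(fit)), pri$mu, tolerance = 1e-3)
})

test_that("alpha scan: layout, normalization, range idempotence", {
  crv <- line_data(seed = 11)
  model <- make_line_model()
  pri <- prior_set(c("b0", "b1"), "gaussian", mu = c(0, 0),
                   sigma = c(2, 2))
  fit <- corefit(crv, model, pri)
  expect_length(fit$alpha, 11)
  expect_equal(sum(fit$prob), 1)
  expect_equal(unname(coef(fit)),
               unname(colSums(fit$prob * fit$par_by_alpha)))
  # deliberately offset initial range: auto-adjustment recovers the same
  # posterior-averaged solution
  fit2 <- suppressWarnings(
    corefit(crv, model, pri, alpha_range = c(1e2, 1e6)))
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-3)
})

test_that("probability-weighted averages follow the weights", {
  pba <- matrix(c(1, 3, 10, 30), 2, 2)
  colnames(pba) <- c("p1", "p2")
  # mass on one alpha
  expect_equal(colSums(c(1, 0) * pba), c(p1 = 1, p2 = 10))
  # uniform over two alphas: arithmetic mean
  expect_equal(colSums(c(0.5, 0.5) * pba), c(p1 = 2, p2 = 20))
})

test_that("refined parameters respect bounds and the per-alpha hull", {
  sim <- sim_pair(seed = 23)
  fit <- suppressWarnings(
    corefit(sim$curves, sim$model, load_priors("Gaussian_good")))
  pri <- fit$priors
  expect_true(all(coef(fit) >= pri$lower - 1e-9))
  expect_true(all(coef(fit) <= pri$upper + 1e-9))
  hull_lo <- apply(fit$par_by_alpha, 2, min)
  hull_hi <- apply(fit$par_by_alpha, 2, max)
  expect_true(all(coef(fit) >= hull_lo - 1e-9 &
                    coef(fit) <= hull_hi + 1e-9))
})

test_that("fitted-object methods are consistent", {
  sim <- sim_pair(seed = 24, M_saxs = 150, M_sans = 40)
  fit <- corefit(sim$curves, sim$model, load_priors("Uniform_5s"))
  expect_s3_class(fit, "corefit")
  expect_output(print(fit), "Simultaneous refinement")
  fv <- fitted(fit)
  expect_length(fv, 2)
  expect_equal(fv[[1]], predict(fit, 1))
  res <- residuals(fit)
  expect_equal(res[[2]],
               (sim$curves[[2]]$I - fv[[2]]) / sim$curves[[2]]$sigma)
  expect_equal(sum(res[[1]]^2), fit$chi2[1])
  V <- vcov(fit)
  expect_true(all(diag(V) > 0))
  expect_equal(rownames(V), names(coef(fit)))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]][[1]], "sas_curve")
  smry <- summary(fit)
  expect_output(print(smry), "reduced chi2")
  expect_equal(sum(smry$datasets$N_g), smry$N_g, tolerance = 1e-9)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("mixture refinement recovers the component fraction", {
  # two distinct component curves on a shared grid, mixed 90:10
  q <- make_qgrid(1e-3, 0.3, 150)
  I_sym <- coreshell_intensity(q, c(10, 30, 50, 70), c(1, 1, 1), a = 1)
  I_asym <- coreshell_intensity(q, c(10, 30, 50, 90), c(1, 2, 1), a = 1)
  comp <- list(list(data.frame(q = q, I = I_sym),
                    data.frame(q = q, I = I_asym)))
  model <- sas_model("mixture", components = comp)
  truth <- c(f1 = 0.9, s.1 = 1.2)
  I_mix <- mixture_intensity(q, I_sym, I_asym, f1 = 0.9, s = 1.2)
  set.seed(31)
  sig <- 0.01 * I_mix + 1e-6
  crv <- sas_curve(q, rnorm(length(q), I_mix, sig), sig, label = "mix")
  # log-normal prior on the component ratio centred on a 50:50 mixture
  pri <- prior_set(c("f1", "s.1"), kind = c("lognormal_ratio", "gaussian"),
                   mu = c(0.5, 1), sigma = c(1, 0.5),
                   lower = c(1e-4, 0.1), upper = c(1 - 1e-4, 10))
  fit <- suppressWarnings(corefit(crv, model, pri))
  se_f1 <- sqrt(vcov(fit)["f1", "f1"])
  expect_lt(abs(coef(fit)[["f1"]] - 0.9), 2 * se_f1 + 0.02)
  expect_equal(coef(fit)[["s.1"]], 1.2, tolerance = 0.05)
  # a 50:50 mixture is the centre of the ratio prior
  expect_equal(prior_penalty(c(f1 = 0.5, s.1 = 1), pri), 0)
})
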