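# Analytic small-angle scattering models: sphere / core-multishell and
# stacked-cylinder form factors, Percus-Yevick hard-sphere structure factor,
# two-component mixture model, and Gaussian resolution smearing.
#
# Conventions: q in 1/Angstrom, lengths in Angstrom, intensities in 1/cm.
# Form factors are normalized to P(0) = 1, so I(q) = a * P(q) [* S(q)] + b
# and the scale a carries the absolute units.

# series switch for sinc-like terms: below this argument use the expansion
.SMALL_ARG <- 1e-4

#' Sphere form-factor amplitude
#'
#' The normalized scattering amplitude of a homogeneous sphere,
#' \eqn{\Phi(qR) = 3[\sin(qR) - qR\cos(qR)]/(qR)^3}, with \eqn{\Phi(0)=1}.
#' A series expansion guards the small-argument limit.
#'
#' @param q momentum transfer (1/Angstrom), non-negative.
#' @param R sphere radius (Angstrom), positive scalar.
#' @return Amplitude values in `[-...,1]`, dimensionless.
#' @examples
#' sphere_amplitude(0, 50)            # 1
#' sphere_amplitude(pi / 50, 50)      # 3/pi^2
#' @export
sphere_amplitude <- function(q, R) {
  if (length(R) != 1 || !is.finite(R) || R <= 0)
    stop("R must be a single positive number")
  if (any(q < 0)) stop("q must be >= 0")
  x <- q * R
  out <- 3 * (sin(x) - x * cos(x)) / (x * x * x)
  i <- which(x < .SMALL_ARG)
  if (length(i)) out[i] <- 1 - x[i]^2 / 10
  out
}

.vol_sphere <- function(R) 4 * pi * R^3 / 3

# Amplitude (un-normalized) and forward amplitude of a core + 3-shell sphere.
# radii: c(R_c, R_1, R_2, R_3); rho: contrasts of (core, shell1..3) relative
# to the core (rho[1] is conventionally 1).
.coreshell_amp <- function(q, radii, rho) {
  A <- 0
  A0 <- 0
  Vprev <- 0
  Fprev <- 0
  for (m in seq_along(radii)) {
    if (radii[m] <= 0) next  # zero volume: no contribution (bound iterates)
    Vm <- .vol_sphere(radii[m])
    Fm <- Vm * sphere_amplitude(q, radii[m])
    A <- A + rho[m] * (Fm - Fprev)
    A0 <- A0 + rho[m] * (Vm - Vprev)
    Vprev <- Vm
    Fprev <- Fm
  }
  list(A = A, A0 = A0)
}

#' Core-multishell sphere intensity
#'
#' Intensity of a spherical particle with a core and three concentric
#' shells: successive-shell differences of volume-weighted sphere
#' amplitudes, coherently summed with their contrasts, squared and
#' normalized so that \eqn{P(0) = 1}; the returned intensity is
#' \eqn{I(q) = a P(q) + b} (optionally \eqn{a P(q) S(q) + b} when a
#' structure factor is supplied).  Only contrasts relative to the core
#' affect the curve shape, so `rho` is expressed relative to the core.
#'
#' @param q momentum-transfer grid (1/Angstrom).
#' @param radii increasing radii `c(R_c, R_1, R_2, R_3)` (Angstrom) of the
#'   core and the outer edge of each shell.
#' @param rho relative contrasts `c(rho1, rho2, rho3)` of the three shells,
#'   each expressed as \eqn{\Delta\rho_j / \Delta\rho_c}.
#' @param a scale (1/cm), positive.
#' @param b constant background (1/cm).
#' @param sq optional structure-factor values on `q` (same length),
#'   multiplied onto `a P(q)`.
#' @param validate check parameter invariants (strictly increasing radii);
#'   internal fitting paths disable this because intermediate iterates may
#'   wander.
#' @return Intensity values (1/cm) on `q`.
#' @examples
#' q <- seq(1e-3, 0.5, length.out = 64)
#' I <- coreshell_intensity(q, c(10, 30, 50, 70), rho = c(2, 3, 4), a = 0.5,
#'                          b = 1e-5)
#' @export
coreshell_intensity <- function(q, radii, rho, a = 1, b = 0, sq = NULL,
                                validate = TRUE) {
  if (validate) {
    if (length(radii) < 2 || any(!is.finite(radii)) || radii[1] <= 0 ||
        any(diff(radii) <= 0))
      stop("radii must be finite, positive and strictly increasing")
    if (a <= 0) stop("scale a must be > 0")
  }
  amp <- .coreshell_amp(q, radii, c(1, rho))
  if (validate &&
      abs(amp$A0) < 1e-12 * sum(abs(c(1, rho))) * .vol_sphere(max(radii)))
    stop("total forward amplitude is zero: model fully matched out")
  P <- (amp$A / amp$A0)^2
  if (!is.null(sq)) P <- P * sq
  a * P + b
}

#' Cylinder form-factor amplitude at fixed orientation
#'
#' Amplitude of a cylinder of radius `R` and length `L` whose axis makes an
#' angle `beta` with the momentum-transfer direction: the product of a
#' radial term \eqn{2 J_1(x)/x} with \eqn{x = qR\sin\beta} and an axial
#' sinc term with argument \eqn{qL\cos\beta/2}; both terms tend to 1 as
#' their argument vanishes.
#'
#' @param q momentum transfer (1/Angstrom).
#' @param R cylinder radius (Angstrom), positive.
#' @param L cylinder length (Angstrom), positive.
#' @param beta orientation angle in `[0, pi/2]` (radians).
#' @return Amplitude values, dimensionless, 1 at `q = 0`.
#' @export
cylinder_amplitude <- function(q, R, L, beta) {
  if (R <= 0 || L <= 0) stop("R and L must be > 0")
  if (any(beta < 0) || any(beta > pi / 2 + 1e-12))
    stop("beta must lie in [0, pi/2]")
  x <- q * R * sin(beta)
  y <- q * L * cos(beta) / 2
  radial <- ifelse(x < .SMALL_ARG, 1 - x^2 / 8, 2 * besselJ(x, 1) / x)
  axial <- ifelse(abs(y) < .SMALL_ARG, 1 - y^2 / 6, sin(y) / y)
  radial * axial
}

# Gauss-Legendre nodes/weights on [0, pi/2] with the sin(beta) Jacobian
# folded into the weights (they then sum to 1 = int_0^{pi/2} sin b db).
.beta_quadrature <- function(n_nodes) {
  gl <- pracma::gaussLegendre(n_nodes, 0, pi / 2)
  list(beta = gl$x, w = gl$w * sin(gl$x))
}

#' Stacked-cylinder intensity
#'
#' Intensity of `n_c` coaxial cylinders stacked contiguously along their
#' common axis (equal radius `R`, lengths `L`, relative contrasts `rho`).
#' The coherent amplitude at orientation \eqn{\beta} is
#' \eqn{\sum_j \rho_j V_j A_j(q,\beta)\, e^{i q \cos\beta\, d_j}} with
#' \eqn{d_j} the center-to-center distance from the first cylinder
#' (\eqn{d_1 = 0}); the modulus squared is averaged over orientations with
#' the \eqn{\sin\beta} weight by fixed Gauss-Legendre quadrature, and the
#' result is normalized to \eqn{P(0)=1}, so \eqn{I = a P + b}.
#'
#' @param q momentum-transfer grid (1/Angstrom).
#' @param R common cylinder radius (Angstrom).
#' @param L cylinder lengths (Angstrom), one per cylinder.
#' @param rho relative contrasts, one per cylinder (the first is the
#'   reference and is conventionally 1).
#' @param a scale (1/cm). @param b constant background (1/cm).
#' @param n_nodes number of quadrature nodes for the orientational average.
#' @param validate check parameter invariants.
#' @return Intensity values (1/cm).
#' @export
stacked_cylinder_intensity <- function(q, R, L, rho = rep(1, length(L)),
                                       a = 1, b = 0, n_nodes = 128,
                                       validate = TRUE) {
  n_c <- length(L)
  if (n_c < 1) stop("need at least one cylinder")
  if (length(rho) != n_c) stop("rho must match length(L)")
  if (validate && (R <= 0 || any(L <= 0)))
    stop("R and all lengths must be > 0")
  R <- abs(R); L <- abs(L)  # fitting iterates may graze zero
  # center-to-center distances for a contiguous stack
  d <- numeric(n_c)
  if (n_c > 1)
    for (j in 2:n_c) d[j] <- L[1] / 2 + sum(L[seq_len(j - 1)][-1]) + L[j] / 2
  V <- pi * R^2 * L
  quad <- .beta_quadrature(n_nodes)
  P <- numeric(length(q))
  cosb <- cos(quad$beta)
  for (i in seq_along(quad$beta)) {
    amp_re <- 0; amp_im <- 0
    for (j in seq_len(n_c)) {
      Aj <- rho[j] * V[j] * cylinder_amplitude(q, R, L[j], quad$beta[i])
      ph <- q * cosb[i] * d[j]
      amp_re <- amp_re + Aj * cos(ph)
      amp_im <- amp_im + Aj * sin(ph)
    }
    P <- P + quad$w[i] * (amp_re^2 + amp_im^2)
  }
  A0 <- sum(rho * V)
  if (abs(A0) < .Machine$double.eps * sum(abs(rho * V)) * 10)
    stop("total forward amplitude is zero: model fully matched out")
  a * P / A0^2 + b
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Closed-form structure factor for hard spheres of radius `R_hs` at volume
#' fraction `eta` in the Percus-Yevick approximation.  `S(q) -> 1` at large
#' `q`; `S(0)` equals the compressibility limit
#' \eqn{(1-\eta)^4/(1+2\eta)^2}.
#'
#' @param q momentum-transfer grid (1/Angstrom).
#' @param R_hs hard-sphere interaction radius (Angstrom), positive.
#' @param eta volume fraction in `[0, 0.74)`.
#' @return `S(q)` values, dimensionless.
#' @export
hardsphere_sq <- function(q, R_hs, eta) {
  if (R_hs <= 0) stop("R_hs must be > 0")
  if (eta < 0 || eta >= 0.74) stop("eta must lie in [0, 0.74)")
  if (eta == 0) return(rep(1, length(q)))
  A <- 2 * q * R_hs
  al <- (1 + 2 * eta)^2 / (1 - eta)^4
  be <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  ga <- eta * al / 2
  S0 <- (1 - eta)^4 / (1 + 2 * eta)^2
  out <- rep(S0, length(q))
  big <- A > 0.02  # below this the closed form loses precision; use S(0)
  Ab <- A[big]
  G <- al * (sin(Ab) - Ab * cos(Ab)) / Ab^2 +
    be * (2 * Ab * sin(Ab) + (2 - Ab^2) * cos(Ab) - 2) / Ab^3 +
    ga * (-Ab^4 * cos(Ab) +
            4 * ((3 * Ab^2 - 6) * cos(Ab) + (Ab^3 - 6 * Ab) * sin(Ab) + 6)) / Ab^5
  out[big] <- 1 / (1 + 24 * eta * G / Ab)
  out
}

#' Two-component mixture intensity
#'
#' Linear mixture of two tabulated component curves on a common q grid:
#' \eqn{I(q) = s\,[f_1 I_1(q) + (1 - f_1) I_2(q)]}.  Used e.g. to fit the
#' fraction of two structural ensembles against data.
#'
#' @param q common q grid of both components.
#' @param I1,I2 component intensities tabulated on `q`.
#' @param f1 fraction of component 1 in `[0, 1]`.
#' @param s overall scale, positive.
#' @param b constant background (default 0).
#' @return Mixed intensity values.
#' @export
mixture_intensity <- function(q, I1, I2, f1, s = 1, b = 0) {
  if (length(I1) != length(q) || length(I2) != length(q))
    stop("component curves must be tabulated on the same q grid")
  if (f1 < 0 || f1 > 1) stop("f1 must lie in [0, 1]")
  if (s <= 0) stop("s must be > 0")
  s * (f1 * I1 + (1 - f1) * I2) + b
}

# ---- Gaussian resolution smearing ------------------------------------------

# Precompute the smearing geometry for a (q, sigma_q) pair: an oversampled
# evaluation grid (5 points per sigma, kernel truncated at +/- 3 sigma and
# renormalized over the positive-q part of its support) plus, per data
# point, the indices and normalized weights into that grid.
smear_setup <- function(q, sigma_q, width = 3, per_sigma = 5) {
  stopifnot(length(sigma_q) == length(q))
  if (any(sigma_q < 0)) stop("sigma_q must be >= 0")
  offs <- seq(-width, width, by = 1 / per_sigma)
  q_eval <- q
  idx <- vector("list", length(q))
  wts <- vector("list", length(q))
  for (i in seq_along(q)) {
    if (sigma_q[i] == 0) {
      idx[[i]] <- i; wts[[i]] <- 1
      next
    }
    nodes <- q[i] + offs * sigma_q[i]
    keep <- nodes > 0
    nodes <- nodes[keep]
    w <- stats::dnorm(offs[keep])
    w <- w / sum(w)
    pos <- length(q_eval) + seq_along(nodes)
    q_eval <- c(q_eval, nodes)
    idx[[i]] <- pos
    wts[[i]] <- w
  }
  list(q = q, q_eval = q_eval, idx = idx, w = wts)
}

smear_apply <- function(setup, I_eval) {
  vapply(seq_along(setup$idx),
         function(i) sum(setup$w[[i]] * I_eval[setup$idx[[i]]]), numeric(1))
}

#' Apply Gaussian q-resolution smearing to a model
#'
#' At each grid point the unsmeared model is averaged over a Gaussian in
#' `q'` with per-point width `sigma_q[i]`, the kernel being truncated at
#' plus/minus 3 widths (on an oversampled grid, 5 nodes per width) and
#' renormalized over its positive-q support.  Points with `sigma_q = 0`
#' are returned unsmeared.  Smearing is linear in the model and conserves
#' a constant curve exactly.
#'
#' @param q momentum-transfer grid.
#' @param model_evaluator function of a q vector returning intensities.
#' @param sigma_q per-point Gaussian resolution widths (1/Angstrom).
#' @return Smeared intensity values on `q`.
#' @export
smear_model <- function(q, model_evaluator, sigma_q) {
  setup <- smear_setup(q, sigma_q)
  smear_apply(setup, model_evaluator(setup$q_eval))
}
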