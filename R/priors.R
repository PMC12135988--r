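# Prior sets: per-parameter prior kind (gaussian / uniform /
# lognormal-ratio), mean, width and truncation bounds, plus the named
# benchmark fixtures for the core-multishell model.

#' Build a prior set
#'
#' A `prior_set` is a data frame with one row per model parameter, columns
#' `par`, `kind` (`"gaussian"`, `"uniform"` or `"lognormal_ratio"`), `mu`
#' (prior mean, also the fit starting value), `sigma` (prior width; for
#' uniform priors a surrogate scale, one tenth of the bound width, used
#' for Hessian normalization and start perturbations) and truncation
#' bounds `lower`/`upper`.  Unless given explicitly, bounds default to
#' `mu +/- 5 sigma`, floored at 0 for positive parameters.
#'
#' @param par parameter names.
#' @param kind prior kinds, recycled.
#' @param mu prior means.
#' @param sigma prior widths (> 0 for gaussian).
#' @param lower,upper optional explicit bounds.
#' @param positive logical, recycled: floor the lower bound at 0.
#' @return An object of class `prior_set` (and `data.frame`).
#' @export
prior_set <- function(par, kind = "gaussian", mu, sigma, lower = NULL,
                      upper = NULL, positive = FALSE) {
  n <- length(par)
  kind <- rep_len(kind, n)
  positive <- rep_len(positive, n)
  if (length(mu) != n || length(sigma) != n)
    stop("mu and sigma must match par")
  if (any(kind == "gaussian" & sigma <= 0))
    stop("gaussian priors need sigma > 0")
  if (is.null(lower)) lower <- mu - 5 * sigma
  if (is.null(upper)) upper <- mu + 5 * sigma
  lower <- ifelse(positive, pmax(0, lower), lower)
  if (any(lower >= upper)) stop("lower bounds must be below upper bounds")
  if (any(mu < lower | mu > upper)) stop("mu must lie within the bounds")
  df <- data.frame(par = par, kind = kind, mu = mu, sigma = sigma,
                   lower = lower, upper = upper,
                   stringsAsFactors = FALSE)
  df$sigma <- ifelse(df$kind == "uniform", (df$upper - df$lower) / 10,
                     df$sigma)
  structure(df, class = c("prior_set", "data.frame"))
}

#' @export
print.prior_set <- function(x, ...) {
  cat(sprintf("<prior_set: %d parameters (%s)>\n", nrow(x),
              paste(unique(x$kind), collapse = ", ")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

# benchmark radii fixtures: sigma_best are the widths of the best Gaussian
# prior; the Uniform_k fixtures narrow the bounds to mu_best +/- k sigma_best
.RADII_TRUTH <- c(R_c = 10, R_1 = 30, R_2 = 50, R_3 = 70)
.SIGMA_BEST <- c(5, 10, 15, 20)
.GAUSS_FIX <- list(
  Gaussian_poor = list(mu = c(5, 40, 45, 90), sigma = c(5, 10, 15, 20)),
  Gaussian_good = list(mu = c(8, 35, 40, 80), sigma = c(4, 10, 20, 10)),
  Gaussian_best = list(mu = c(10, 30, 50, 70), sigma = c(5, 10, 15, 20)))

.radii_prior <- function(name) {
  if (name %in% names(.GAUSS_FIX)) {
    g <- .GAUSS_FIX[[name]]
    return(prior_set(names(.RADII_TRUTH), "gaussian", g$mu, g$sigma,
                     positive = TRUE))
  }
  kk <- switch(name, Uniform_5s = 5, Uniform_4s = 4, Uniform_3s = 3,
               Uniform_2s = 2, Uniform_1s = 1, "Uniform_0.5s" = 0.5,
               stop("unknown prior fixture '", name, "'; available: ",
                    paste(prior_fixtures(), collapse = ", ")))
  prior_set(names(.RADII_TRUTH), "uniform", unname(.RADII_TRUTH),
            .SIGMA_BEST,
            lower = pmax(0, .RADII_TRUTH - kk * .SIGMA_BEST),
            upper = .RADII_TRUTH + kk * .SIGMA_BEST, positive = TRUE)
}

#' Names of the packaged prior fixtures
#' @return Character vector of fixture names accepted by [load_priors()].
#' @export
prior_fixtures <- function() c(paste0("Uniform_", c(5:1, 0.5), "s"),
                               names(.GAUSS_FIX))

# per-dataset nuisance priors by contrast role.  Bounds are explicit where
# the benchmark tables deviate from mu +/- 5 sigma (a for the SANS role).
.nuisance_prior <- function(role, suffix, kind_radii) {
  kind <- if (kind_radii == "uniform") "uniform" else "gaussian"
  tab <- switch(role,
    saxs = list(rho = c(2, 3, 4), rho_sig = c(0.2, 0.3, 0.4),
                a = 0.5, a_sig = 0.05, a_lo = 0.25, a_hi = 0.75,
                b = 1e-5),
    sans = list(rho = c(-0.1, 0.1, 0.05), rho_sig = c(0.01, 0.01, 0.005),
                a = 0.8, a_sig = 0.08, a_lo = 0.1, a_hi = 0.9,
                b = 1e-4),
    core = list(rho = c(0, 0, 0), rho_sig = c(0.01, 0.01, 0.01),
                a = 0.8, a_sig = 0.08, a_lo = 0.1, a_hi = 0.9,
                b = 1e-4),
    stop("unknown dataset role: ", role))
  prior_set(
    par = paste(c("rho1", "rho2", "rho3", "a", "b"), suffix, sep = "."),
    kind = kind,
    mu = c(tab$rho, tab$a, tab$b),
    sigma = c(tab$rho_sig, tab$a_sig, 1e-2),
    lower = c(tab$rho - 5 * tab$rho_sig, tab$a_lo, tab$b - 5e-2),
    upper = c(tab$rho + 5 * tab$rho_sig, tab$a_hi, tab$b + 5e-2))
}

#' Load a packaged prior fixture for the core-multishell benchmark
#'
#' Builds the full joint prior set for a multi-dataset core-multishell
#' refinement: the named radii fixture (`"Uniform_5s"` ... `"Uniform_0.5s"`
#' narrowing uniform bounds, or `"Gaussian_poor"/"Gaussian_good"/
#' "Gaussian_best"`) combined with the standard nuisance priors (relative
#' contrasts, scale, background) for each dataset's contrast role.  For
#' Gaussian radii fixtures the nuisance priors are Gaussian too; for
#' uniform fixtures only the bounds act.
#'
#' @param name radii fixture name; see [prior_fixtures()].
#' @param roles contrast role per dataset: `"saxs"`, `"sans"`, or `"core"`
#'   (a SANS-like dataset in which only the core has non-zero contrast).
#' @return A [prior_set] covering [model_par_names()] of `coreshell3`.
#' @examples
#' load_priors("Gaussian_best", roles = c("saxs", "sans"))
#' @export
load_priors <- function(name = "Uniform_5s", roles = c("saxs", "sans")) {
  radii <- .radii_prior(name)
  pieces <- lapply(seq_along(roles), function(j)
    .nuisance_prior(roles[j], j, radii$kind[1]))
  out <- do.call(rbind, c(list(radii), pieces))
  structure(out, class = c("prior_set", "data.frame"))
}

#' True benchmark parameter values
#'
#' The ground-truth parameter vector used throughout the synthetic
#' benchmarks: radii 10/30/50/70 Angstrom; per dataset the role-specific
#' true contrasts, scale and background (SAXS: contrasts 2/3/4, a = 0.5,
#' b = 1e-5; SANS: contrasts -0.1/0.1/0.05, a = 0.8, b = 1e-4; core role:
#' zero shell contrasts with SANS-like scale and background).
#'
#' @param roles contrast role per dataset.
#' @return Named numeric vector laid out as [model_par_names()].
#' @export
truth_coreshell <- function(roles = c("saxs", "sans")) {
  vals <- lapply(seq_along(roles), function(j) {
    v <- switch(roles[j],
      saxs = c(2, 3, 4, 0.5, 1e-5),
      sans = c(-0.1, 0.1, 0.05, 0.8, 1e-4),
      core = c(0, 0, 0, 0.8, 1e-4),
      stop("unknown dataset role: ", roles[j]))
    names(v) <- paste(c("rho1", "rho2", "rho3", "a", "b"), j, sep = ".")
    v
  })
  c(.RADII_TRUTH, unlist(vals))
}

#' True parameter values for the stacked-cylinder benchmark
#'
#' Ground truth for the stacked-cylinder synthetic benchmark: common
#' radius 30 Angstrom, lengths 40/100/60 Angstrom, and per-dataset
#' relative contrasts chosen to emulate complementary SAXS/SANS contrast
#' situations.
#'
#' @param roles contrast role per dataset (`"saxs"` or `"sans"`).
#' @return Named numeric vector laid out as [model_par_names()].
#' @export
truth_stackedcyl <- function(roles = c("saxs", "sans")) {
  vals <- lapply(seq_along(roles), function(j) {
    v <- switch(roles[j],
      saxs = c(2, 3, 0.5, 1e-5),
      sans = c(-0.5, 0.25, 0.8, 1e-4),
      stop("unknown dataset role: ", roles[j]))
    names(v) <- paste(c("rho2", "rho3", "a", "b"), j, sep = ".")
    v
  })
  c(c(R = 30, L_1 = 40, L_2 = 100, L_3 = 60), unlist(vals))
}

#' Prior set for the stacked-cylinder benchmark
#'
#' Gaussian or uniform priors centred on [truth_stackedcyl()] with widths
#' of 5 Angstrom on the radius, 10/20/15 Angstrom on the lengths and 10
#' percent on the contrasts and scales; bounds are mu +/- 5 sigma floored
#' at zero for positive parameters.
#'
#' @param roles contrast role per dataset.
#' @param kind `"uniform"` or `"gaussian"`.
#' @return A [prior_set].
#' @export
priors_stackedcyl <- function(roles = c("saxs", "sans"), kind = "uniform") {
  truth <- truth_stackedcyl(roles)
  sig <- c(5, 10, 20, 15,
           unlist(lapply(roles, function(r)
             switch(r, saxs = c(0.2, 0.3, 0.05, 1e-2),
                    sans = c(0.05, 0.025, 0.08, 1e-2)))))
  prior_set(names(truth), kind, unname(truth), unname(sig),
            positive = names(truth) %in% c("R", "L_1", "L_2", "L_3"))
}
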