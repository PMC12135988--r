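# Simultaneous weighted refinement of multiple curves with truncated
# Gaussian (or uniform) priors.  The objective is
#     Q = sum_j w_j chi2_j + alpha S,
# realized as bounded Levenberg-Marquardt least squares on a stacked
# residual vector: data residuals with errors scaled by 1/sqrt(w_j), plus
# one dummy residual per Gaussian-prior parameter with error
# sigma_prior / sqrt(alpha).  The hyperparameter alpha is selected by
# scanning 11 log-spaced values and weighting by the (Laplace) evidence.

#' Error-weighted chi-square of a model against a curve
#'
#' \eqn{\chi^2 = \sum_i (I_i - I_{model,i})^2 / \sigma_i^2}.
#'
#' @param curve a [sas_curve]. @param model_values intensities on the
#'   curve's q grid.
#' @return The (non-reduced) chi-square.
#' @export
chi2 <- function(curve, model_values) {
  stopifnot(inherits(curve, "sas_curve"))
  if (length(model_values) != nrow(curve))
    stop("model values must match the curve length")
  if (any(curve$sigma <= 0)) stop("curve has non-positive errors")
  sum(((curve$I - model_values) / curve$sigma)^2)
}

#' Gaussian prior penalty
#'
#' \eqn{S = \sum_k [(x_k - \mu_{prior,k})/\sigma_{prior,k}]^2} over the
#' Gaussian-prior parameters (uniform-prior parameters contribute zero;
#' a `lognormal_ratio` prior on a fraction parameter `x` contributes
#' \eqn{[\log((1-x)/x)/\sigma]^2}, a log-normal prior on the ratio
#' `(1-x)/x` centred on 1).
#'
#' @param x named parameter vector. @param priors a [prior_set].
#' @return The penalty `S`, dimensionless.
#' @export
prior_penalty <- function(x, priors) {
  sum(.prior_residuals(x[priors$par], priors)^2)
}

# residual vector contributed by the priors (before the sqrt(alpha) factor)
.prior_residuals <- function(x, priors) {
  r <- numeric(0)
  g <- priors$kind == "gaussian"
  if (any(g)) r <- c(r, (x[g] - priors$mu[g]) / priors$sigma[g])
  ln <- priors$kind == "lognormal_ratio"
  if (any(ln)) {
    xr <- pmin(pmax(x[ln], 1e-12), 1 - 1e-12)
    r <- c(r, log((1 - xr) / xr) / priors$sigma[ln])
  }
  unname(r)
}

#' Per-dataset weights of a weighting scheme
#'
#' The three schemes compared in the benchmarks: `naive` (`w_j = 1`, each
#' point weighted only by its own error), `reduced` (`w_j = 1/M_j`, every
#' dataset gets equal total weight, akin to summing reduced chi-squares)
#' and `information` (`w_j = N_g,BIFT,j / M_j`, each dataset weighted by
#' its information content per point, with `N_g,BIFT` estimated by the
#' embedded [bift()]).  Weights are realized by scaling each dataset's
#' errors with `1/sqrt(w_j)`, so ordinary least squares on the scaled
#' errors minimizes `sum_j w_j chi2_j`; multiplying all `w_j` by a common
#' constant leaves the minimizer unchanged.
#'
#' @param curves list of [sas_curve]s.
#' @param scheme `"naive"`, `"reduced"`, or `"information"`.
#' @param ng_bift optional precomputed `N_g,BIFT` per dataset (recomputing
#'   per replicate is the default elsewhere; pass values here to reuse
#'   them across fits).
#' @return Positive weights, one per dataset.
#' @export
scheme_weights <- function(curves, scheme = c("naive", "reduced",
                                              "information"),
                           ng_bift = NULL) {
  scheme <- match.arg(scheme)
  M <- vapply(curves, nrow, integer(1))
  w <- switch(scheme,
    naive = rep(1, length(curves)),
    reduced = 1 / M,
    information = {
      if (is.null(ng_bift))
        ng_bift <- vapply(curves, function(cc) bift(cc)$ng, numeric(1))
      if (length(ng_bift) != length(curves))
        stop("ng_bift must have one value per dataset")
      ng_bift / M
    })
  if (any(w <= 0)) stop("all weights must be > 0")
  w
}

# Precompute everything the residual function needs: per-dataset scaled
# errors, smearing setups, and the prior layout aligned with the model's
# parameter order.
.fit_env <- function(curves, model, priors, w) {
  nd <- length(curves)
  par_names <- model_par_names(model, nd)
  pr <- as.data.frame(priors)
  if (!setequal(pr$par, par_names))
    stop("priors must cover exactly the model parameters: ",
         paste(par_names, collapse = ", "))
  pr <- pr[match(par_names, pr$par), ]
  sets <- lapply(seq_len(nd), function(j) {
    crv <- curves[[j]]
    sm <- if (!is.null(crv$sigma_q) && any(crv$sigma_q > 0))
      smear_setup(crv$q, crv$sigma_q) else NULL
    list(crv = crv, sm = sm, sig_w = crv$sigma / sqrt(w[j]))
  })
  eval_j <- function(theta, j) {
    s <- sets[[j]]
    if (is.null(s$sm)) model_intensity(model, s$crv$q, theta, j)
    else smear_apply(s$sm, model_intensity(model, s$sm$q_eval, theta, j))
  }
  n_resid <- sum(vapply(sets, function(s) nrow(s$crv), integer(1))) +
    length(.prior_residuals(stats::setNames(pr$mu, par_names), pr))
  resid_fn <- function(theta, alpha) {
    theta <- stats::setNames(theta, par_names)
    if (any(!is.finite(theta))) return(rep(1e8, n_resid))
    r <- unlist(lapply(seq_len(nd), function(j) {
      s <- sets[[j]]
      (s$crv$I - eval_j(theta, j)) / s$sig_w
    }), use.names = FALSE)
    rp <- sqrt(alpha) * .prior_residuals(theta, pr)
    out <- c(r, rp)
    out[!is.finite(out)] <- 1e8  # keep LM alive through degenerate iterates
    out
  }
  list(par_names = par_names, priors = pr, sets = sets, eval_j = eval_j,
       resid_fn = resid_fn, nd = nd)
}

# One bounded LM fit of Q = sum_j w_j chi2_j + alpha S.  Starts at the
# prior means unless 'start' is given; retries from slightly perturbed
# starts (up to 3 times, +/- 1 percent of the prior widths) on failure.
.fit_at_alpha <- function(env, alpha, start = NULL,
                          control = minpack.lm::nls.lm.control(maxiter = 200)) {
  pr <- env$priors
  start0 <- if (is.null(start)) stats::setNames(pr$mu, env$par_names)
            else start[env$par_names]
  attempt <- 0
  repeat {
    st <- pmin(pmax(start0, pr$lower), pr$upper)
    fit <- minpack.lm::nls.lm(par = st, lower = pr$lower, upper = pr$upper,
                              fn = env$resid_fn, alpha = alpha,
                              control = control)
    ok <- fit$info %in% 1:4 && all(is.finite(fit$par))
    if (ok || attempt >= 3) break
    attempt <- attempt + 1
    start0 <- start0 + 0.01 * pr$sigma * stats::rnorm(length(start0))
  }
  theta <- stats::setNames(fit$par, env$par_names)
  if (any(!is.finite(theta))) {  # never propagate a degenerate iterate
    theta <- stats::setNames(pmin(pmax(pr$mu, pr$lower), pr$upper),
                             env$par_names)
    fit$info <- 0L
  }
  chi2_j <- vapply(seq_len(env$nd), function(j) {
    s <- env$sets[[j]]
    sum(((s$crv$I - env$eval_j(theta, j)) / s$crv$sigma)^2)
  }, numeric(1))
  S <- prior_penalty(theta, env$priors)
  Q <- sum(fit$deviance)
  if (!is.finite(Q)) Q <- sum(env$resid_fn(theta, alpha)^2)
  list(par = theta, Q = Q, chi2 = chi2_j, S = S,
       hessian = fit$hessian,  # J'J: Hessian of Q/2 (Gauss-Newton)
       converged = fit$info %in% 1:4, info = fit$info, niter = fit$niter,
       message = fit$message)
}

# Laplace-approximation log-evidence of the solution at one alpha, up to a
# constant shared across the scan:
#   log p(alpha) = -Q/2 + (K_g/2) log(alpha) - 1/2 log det(S^(1/2) A S^(1/2))
# with A the Gauss-Newton Hessian of Q/2 (data + prior rows) and S^(1/2)
# the prior-width normalization; K_g counts the parameters with an
# alpha-scaled prior.
.log_evidence <- function(fit, priors, alpha) {
  if (!is.finite(fit$Q) || any(!is.finite(fit$hessian))) return(-Inf)
  Kg <- sum(priors$kind != "uniform")
  sig <- priors$sigma
  B <- fit$hessian * outer(sig, sig)
  ld <- determinant(B, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) {
    # a parameter pinned at a bound yields a zero Hessian row; an
    # indefinite Hessian signals a saddle -- regularize either way
    if (ld$sign <= 0)
      warning("singular posterior Hessian; regularizing determinant")
    ld <- determinant(B + diag(1e-8 * max(diag(B), 1), nrow(B)),
                      logarithm = TRUE)
    if (!is.finite(ld$modulus)) return(-Inf)
  }
  -fit$Q / 2 + Kg / 2 * log(alpha) - as.numeric(ld$modulus) / 2
}

# Multistart helper: refit from a few prior-width-scale jitters of the
# prior means and keep the lowest-Q solution.  Guards the scan against the
# starting point sitting in a poor local basin of the likelihood.
.best_of_starts <- function(env, alpha, f, n_starts, control,
                            stall_limit = 10) {
  pr <- env$priors
  stall <- 0
  for (s in seq_len(max(0, n_starts - 1))) {
    st <- stats::setNames(pr$mu + pr$sigma * stats::rnorm(nrow(pr)),
                          pr$par)
    fs <- .fit_at_alpha(env, alpha, start = st, control = control)
    if (is.finite(fs$Q) && fs$Q < f$Q - 0.5) {
      f <- fs; stall <- 0
    } else stall <- stall + 1
    if (stall >= stall_limit) break
  }
  f
}

# 11-point logarithmic alpha scan with boundary auto-adjustment: if the
# evidence maximum lands on an end of the scanned range, the whole range
# is shifted by half a decade toward it and the scan repeats (bounded
# number of shifts).  Fits are warm-started from the neighbouring alpha.
.alpha_scan <- function(env, alpha_range, n_alpha = 11, max_shift = 6,
                        n_starts = 25,
                        control = minpack.lm::nls.lm.control(maxiter = 200)) {
  lo <- log10(alpha_range[1]); hi <- log10(alpha_range[2])
  shifts <- 0
  repeat {
    alphas <- 10^seq(lo, hi, length.out = n_alpha)
    # each alpha is fitted from the prior means (the configured initial
    # guess) and, additionally, warm-started from the neighbouring
    # stronger-prior solution; the lower-Q minimum wins.  The second start
    # guards against local minima when the prior means sit in a poor basin.
    fits <- vector("list", n_alpha)
    warm <- NULL
    for (i in rev(seq_len(n_alpha))) {
      f <- .fit_at_alpha(env, alphas[i], control = control)
      if (i == 1)  # weak-regularization anchor: explore around the start
        f <- .best_of_starts(env, alphas[i], f, n_starts, control)
      if (!is.null(warm)) {
        fw <- .fit_at_alpha(env, alphas[i], start = warm,
                            control = control)
        if (is.finite(fw$Q) && fw$Q < f$Q) f <- fw
      }
      warm <- f$par
      fits[[i]] <- f
    }
    # ascending pass: let a data-driven basin found at weak regularization
    # propagate towards the strong-prior end as well
    for (i in seq_len(n_alpha)[-1]) {
      fw <- .fit_at_alpha(env, alphas[i], start = fits[[i - 1]]$par,
                          control = control)
      if (is.finite(fw$Q) && fw$Q < fits[[i]]$Q) fits[[i]] <- fw
    }
    logp <- vapply(seq_len(n_alpha), function(i)
      .log_evidence(fits[[i]], env$priors, alphas[i]), numeric(1))
    imax <- which.max(logp)
    interior <- imax > 1 && imax < n_alpha
    # evidence plateaus at large alpha when the prior mean already fits the
    # data as well as any refinement; treat a flat upper end as converged
    plateau <- imax == n_alpha &&
      (logp[n_alpha] - logp[n_alpha - 1]) < 0.05
    if (interior || plateau || shifts >= max_shift) {
      interior <- interior || plateau
      break
    }
    step <- (hi - lo) / 2
    if (imax == 1) { lo <- lo - step; hi <- hi - step }
    else { lo <- lo + step; hi <- hi + step }
    shifts <- shifts + 1
  }
  if (!any(is.finite(logp))) {
    warning("no alpha in the scan produced a converged fit")
    p <- rep(1 / n_alpha, n_alpha)
  } else {
    p <- exp(logp - max(logp[is.finite(logp)]))
    p <- p / sum(p)
  }
  list(alpha = alphas, logp = logp, prob = p, fits = fits, imax = imax,
       adjusted = shifts, interior = interior)
}

#' Simultaneously refine a model against one or more scattering curves
#'
#' Fits a shared analytic model to several datasets at once by minimizing
#' the weighted objective \eqn{Q = \sum_j w_j \chi^2_j + \alpha S}, where
#' the per-dataset weights \eqn{w_j} follow the chosen scheme (see
#' [scheme_weights()]) and `S` is the Gaussian prior penalty.  With
#' uniform priors (`kind = "uniform"` throughout) the prior is quenched by
#' fixing \eqn{\alpha = 10^{-10}} — only the bounds and starting values
#' act, i.e. bounded maximum likelihood.  With Gaussian priors, 11
#' log-spaced \eqn{\alpha} values are scanned (range auto-adjusted until
#' the evidence maximum is interior), each refined parameter is reported
#' as the probability-weighted average over the scan, and the
#' \eqn{\alpha} table is kept in the returned object.
#'
#' Curves carrying a `sigma_q` column are Gaussian-smeared consistently
#' during fitting.
#'
#' @param curves a [sas_curve] or list of them.
#' @param model a [sas_model].
#' @param priors a [prior_set] covering [model_par_names()]; prior means
#'   are the starting values, bounds constrain the fit.
#' @param scheme weighting scheme: `"naive"`, `"reduced"` or
#'   `"information"`.
#' @param alpha fix the regularization weight instead of scanning
#'   (`1e-10` is forced for all-uniform priors).
#' @param alpha_range initial scan range (log-spaced), auto-adjusted.
#' @param n_alpha number of alpha values in the scan.
#' @param weights explicit per-dataset weights overriding `scheme`.
#' @param ng_bift precomputed per-dataset `N_g,BIFT` for the information
#'   scheme (otherwise computed by the embedded [bift()]).
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return An object of class `corefit`; see [summary.corefit()].
#'   Components include `coefficients` (probability-averaged for Gaussian
#'   priors), `chi2` per dataset, `weights`, and for scanned fits the
#'   tables `alpha`, `prob` and `par_by_alpha`.
#' @examples
#' m <- sas_model("coreshell3")
#' th <- truth_coreshell()
#' q1 <- make_qgrid(1e-3, 0.5, 400); q2 <- make_qgrid(1e-3, 0.5, 50)
#' curves <- list(
#'   simulate_dataset(m, th, 1, q1, noise_spec("saxs"), seed = 11,
#'                    label = "SAXS"),
#'   simulate_dataset(m, th, 2, q2, noise_spec("sans"), seed = 12,
#'                    label = "SANS"))
#' fit <- corefit(curves, m, load_priors("Uniform_5s"))
#' coef(fit)[1:4]
#' @export
corefit <- function(curves, model, priors,
                    scheme = c("naive", "reduced", "information"),
                    alpha = NULL, alpha_range = c(1e-2, 1e2), n_alpha = 11,
                    weights = NULL, ng_bift = NULL,
                    control = minpack.lm::nls.lm.control(maxiter = 200)) {
  if (inherits(curves, "sas_curve")) curves <- list(curves)
  scheme <- match.arg(scheme)
  stopifnot(inherits(model, "sas_model"), inherits(priors, "prior_set"))
  w <- weights %||% scheme_weights(curves, scheme, ng_bift = ng_bift)
  env <- .fit_env(curves, model, priors, w)
  uniform <- all(env$priors$kind == "uniform")
  out <- list(model = model, curves = curves, priors = env$priors,
              scheme = scheme, weights = w,
              M = vapply(curves, nrow, integer(1)),
              labels = vapply(curves, curve_label, character(1)),
              uniform = uniform, env = env)
  if (uniform || !is.null(alpha)) {
    a <- alpha %||% 1e-10
    fit <- .fit_at_alpha(env, a, control = control)
    out$coefficients <- fit$par
    out$alpha <- a
    out$prob <- 1
    out$par_by_alpha <- matrix(fit$par, nrow = 1,
                               dimnames = list(NULL, env$par_names))
    out$fit <- fit
  } else {
    scan <- .alpha_scan(env, alpha_range, n_alpha, control = control)
    if (!scan$interior)
      warning("alpha range adjustment limit reached; ",
              "evidence maximum may sit on the scan boundary")
    pba <- t(vapply(scan$fits, `[[`, numeric(length(env$par_names)),
                    "par"))
    colnames(pba) <- env$par_names
    out$coefficients <- stats::setNames(colSums(scan$prob * pba),
                                        env$par_names)
    out$alpha <- scan$alpha
    out$prob <- scan$prob
    out$logp <- scan$logp
    out$par_by_alpha <- pba
    out$fit <- scan$fits[[scan$imax]]
    out$alpha_adjusted <- scan$adjusted
  }
  out$converged <- out$fit$converged
  out$chi2 <- vapply(seq_along(curves), function(j) {
    s <- env$sets[[j]]
    sum(((s$crv$I - env$eval_j(out$coefficients, j)) / s$crv$sigma)^2)
  }, numeric(1))
  out$S <- prior_penalty(out$coefficients, env$priors)
  class(out) <- "corefit"
  out
}
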