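# S3 methods for corefit objects.

#' @export
print.corefit <- function(x, ...) {
  cat(sprintf("Simultaneous refinement: model '%s', %d dataset(s), scheme '%s'\n",
              x$model$name, length(x$curves), x$scheme))
  if (x$uniform)
    cat("Priors: uniform (bounds only, alpha quenched at 1e-10)\n")
  else
    cat(sprintf("Priors: Gaussian; alpha scan over [%.3g, %.3g], MAP alpha = %.3g\n",
                min(x$alpha), max(x$alpha), x$alpha[which.max(x$prob)]))
  cat("Coefficients (probability-averaged):\n")
  print(round(x$coefficients, 5))
  cat(sprintf("chi2 per dataset: %s  (M: %s)\n",
              paste(sprintf("%.1f", x$chi2), collapse = ", "),
              paste(x$M, collapse = ", ")))
  if (!x$converged) cat("WARNING: fit flagged as not converged\n")
  invisible(x)
}

#' @export
coef.corefit <- function(object, ...) object$coefficients

#' @export
vcov.corefit <- function(object, ...) {
  A <- object$fit$hessian  # Gauss-Newton Hessian of Q/2
  V <- tryCatch(chol2inv(chol(A)), error = function(e)
    solve(A + diag(1e-10 * max(diag(A)), nrow(A))))
  dimnames(V) <- list(names(object$coefficients),
                      names(object$coefficients))
  V
}

#' Model curves of a fitted co-refinement
#'
#' @param object a [corefit] object.
#' @param dataset dataset index.
#' @param q optional new q grid (unsmeared evaluation); default is the
#'   dataset's own grid with its resolution smearing applied.
#' @param ... unused.
#' @return Intensity values.
#' @export
predict.corefit <- function(object, dataset = 1, q = NULL, ...) {
  if (is.null(q))
    return(object$env$eval_j(object$coefficients, dataset))
  model_intensity(object$model, q, object$coefficients, dataset)
}

#' @export
fitted.corefit <- function(object, ...)
  lapply(seq_along(object$curves), function(j)
    object$env$eval_j(object$coefficients, j))

#' Residuals of a fitted co-refinement
#'
#' @param object a [corefit] object.
#' @param type `"pearson"` (error-normalized, default) or `"response"`.
#' @param ... unused.
#' @return List of residual vectors, one per dataset.
#' @export
residuals.corefit <- function(object, type = c("pearson", "response"),
                              ...) {
  type <- match.arg(type)
  fv <- fitted(object)
  lapply(seq_along(object$curves), function(j) {
    r <- object$curves[[j]]$I - fv[[j]]
    if (type == "pearson") r / object$curves[[j]]$sigma else r
  })
}

#' Parametric re-simulation from a fitted co-refinement
#'
#' Draws new synthetic datasets around the fitted model curves using each
#' curve's reported errors as the sampling standard deviations (a
#' parametric bootstrap of the experiment).
#'
#' @param object a [corefit] object.
#' @param nsim number of replicate dataset lists.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of length `nsim`; each element is a list of
#'   [sas_curve]s mirroring the fitted datasets.
#' @export
simulate.corefit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fv <- fitted(object)
  lapply(seq_len(nsim), function(r)
    lapply(seq_along(object$curves), function(j) {
      crv <- object$curves[[j]]
      sas_curve(crv$q, stats::rnorm(nrow(crv), fv[[j]], crv$sigma),
                crv$sigma, sigma_q = crv$sigma_q,
                label = paste0(curve_label(crv), "_sim", r))
    }))
}

#' Summary of a co-refinement, with information-content bookkeeping
#'
#' Computes, at the refined parameters: the forward-difference Hessian of
#' the weighted chi-square, the total number of good parameters
#' \eqn{N_g} at the selected alpha, each dataset's stand-alone
#' upper-limit count \eqn{n_{g,j}}, the proportional DOF partition
#' (see [dof_partition()]), and per-dataset reduced chi-squares.
#' Parameter standard errors come from the Gauss-Newton covariance.
#'
#' @param object a [corefit] object.
#' @param ... unused.
#' @return An object of class `summary.corefit` with elements
#'   `coefficients` (estimate, prior mean/width, SE), `datasets` (the DOF
#'   partition table), `N_g`, `chi2_reduced_total`, and the alpha table
#'   for scanned fits.
#' @export
summary.corefit <- function(object, ...) {
  th <- object$coefficients
  pr <- object$priors
  alpha_hat <- if (object$uniform) 1e-10
               else object$alpha[which.max(object$prob)]
  # joint weighted chi-square Hessian -> total N_g
  wchi2 <- function(x) {
    x <- stats::setNames(x, names(th))
    sum(object$weights * vapply(seq_along(object$curves), function(j) {
      s <- object$env$sets[[j]]
      sum(((s$crv$I - object$env$eval_j(x, j)) / s$crv$sigma)^2)
    }, numeric(1)))
  }
  H <- numeric_hessian(wchi2, th)
  Ng_tot <- ng_from_hessian(H, pr$sigma, alpha_hat)
  # per-dataset upper limits n_g,j
  ngj <- vapply(seq_along(object$curves), function(j) {
    fj <- function(x) {
      x <- stats::setNames(x, names(th))
      s <- object$env$sets[[j]]
      sum(((s$crv$I - object$env$eval_j(x, j)) / s$crv$sigma)^2)
    }
    ng_from_hessian(numeric_hessian(fj, th), pr$sigma, alpha_hat)
  }, numeric(1))
  Ng_tot <- min(Ng_tot, sum(ngj))
  dt <- dof_partition(ngj, Ng_tot, object$M, chi2 = object$chi2)
  dt <- cbind(label = object$labels, weight = object$weights, dt)
  se <- sqrt(pmax(diag(vcov(object)), 0))
  out <- list(
    model = object$model$name, scheme = object$scheme,
    uniform = object$uniform,
    coefficients = data.frame(estimate = th, se = se, prior_mu = pr$mu,
                              prior_sigma = pr$sigma, kind = pr$kind,
                              row.names = names(th)),
    datasets = dt, N_g = Ng_tot,
    chi2_total = sum(object$chi2),
    chi2_reduced_total = sum(object$chi2) / (sum(object$M) - Ng_tot),
    alpha = object$alpha, prob = object$prob,
    converged = object$converged)
  class(out) <- "summary.corefit"
  out
}

#' @export
print.summary.corefit <- function(x, ...) {
  cat(sprintf("Co-refinement summary: model '%s', scheme '%s'%s\n",
              x$model, x$scheme,
              if (x$uniform) ", uniform priors" else ", Gaussian priors"))
  cat("\nCoefficients:\n")
  print(format(x$coefficients, digits = 4))
  cat("\nDatasets (DOF partitioned by information content):\n")
  print(format(x$datasets, digits = 4))
  cat(sprintf("\nTotal N_g = %.2f; total reduced chi2 = %.3f\n",
              x$N_g, x$chi2_reduced_total))
  if (length(x$alpha) > 1) {
    cat("\nalpha scan (probability):\n")
    print(round(stats::setNames(x$prob, signif(x$alpha, 3)), 4))
  }
  invisible(x)
}

#' Plot a fitted co-refinement
#'
#' Log-log overlay of the data (with error bars) and the fitted model
#' curves, one colour per dataset, with a normalized-residual panel
#' below.
#'
#' @param x a [corefit] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.corefit <- function(x, ...) {
  fv <- fitted(x)
  op <- graphics::par(mfrow = c(2, 1), mar = c(0.5, 4, 2, 1))
  on.exit(graphics::par(op))
  allI <- unlist(lapply(x$curves, function(cc) cc$I))
  allq <- unlist(lapply(x$curves, function(cc) cc$q))
  pos <- allI > 0
  graphics::plot(range(allq), range(allI[pos]), log = "xy", type = "n",
                 xlab = "", ylab = "I(q) (1/cm)", xaxt = "n", ...)
  for (j in seq_along(x$curves)) {
    crv <- x$curves[[j]]
    keep <- crv$I > 0
    graphics::points(crv$q[keep], crv$I[keep], col = j + 1, pch = 16,
                     cex = 0.4)
    graphics::lines(crv$q, pmax(fv[[j]], min(allI[pos])), col = j + 1,
                    lwd = 2)
  }
  graphics::legend("bottomleft", legend = x$labels, col = seq_along(x$curves) + 1,
                   lty = 1, bty = "n", cex = 0.8)
  graphics::par(mar = c(4, 4, 0.5, 1))
  res <- residuals(x)
  graphics::plot(range(allq), range(unlist(res)), log = "x", type = "n",
                 xlab = "q (1/A)", ylab = "(I - fit)/sigma")
  graphics::abline(h = 0, lty = 3)
  for (j in seq_along(res))
    graphics::points(x$curves[[j]]$q, res[[j]], col = j + 1, pch = 16,
                     cex = 0.4)
  invisible(x)
}
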