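# Information-content machinery: forward-difference Hessians, the number
# of good parameters from the prior-normalized eigenspectrum, Shannon
# channels, and the DOF partition for per-dataset reduced chi-squares.

#' Forward-difference Hessian of a scalar objective
#'
#' Second derivatives by one-sided (forward) differences,
#' \eqn{H_{kl} = [f(x + h_k e_k + h_l e_l) - f(x + h_k e_k) -
#' f(x + h_l e_l) + f(x)] / (h_k h_l)}, symmetrized.  Step sizes are
#' relative to the parameter scale.  One-sided differences mirror the
#' convention of the reference implementation; a central-difference
#' cross-check is part of the test suite.
#'
#' @param fn scalar objective taking a parameter vector.
#' @param x evaluation point (named or not).
#' @param rel_step relative step size (default 1e-4 of each parameter's
#'   magnitude, floored by `abs_floor` for near-zero parameters).
#' @param abs_floor absolute step floor.
#' @return Symmetric numeric matrix.
#' @export
numeric_hessian <- function(fn, x, rel_step = 1e-4, abs_floor = 1e-7) {
  K <- length(x)
  h <- pmax(abs(x) * rel_step, abs_floor)
  f0 <- fn(x)
  if (!is.finite(f0)) stop("objective not finite at the expansion point")
  f1 <- numeric(K)
  for (k in seq_len(K)) {
    xk <- x; xk[k] <- xk[k] + h[k]
    f1[k] <- fn(xk)
    if (!is.finite(f1[k]))
      stop("objective not finite when stepping parameter ",
           if (!is.null(names(x))) names(x)[k] else k)
  }
  H <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in k:K) {
    xkl <- x; xkl[k] <- xkl[k] + h[k]; xkl[l] <- xkl[l] + h[l]
    fkl <- fn(xkl)
    if (!is.finite(fkl))
      stop("objective not finite when stepping parameters ", k, ",", l)
    H[k, l] <- H[l, k] <- (fkl - f1[k] - f1[l] + f0) / (h[k] * h[l])
  }
  H <- (H + t(H)) / 2
  dimnames(H) <- list(names(x), names(x))
  H
}

#' Number of good parameters from a model-fit Hessian
#'
#' Normalizes the chi-square Hessian by the prior widths,
#' \eqn{B_{kl} = H_{kl} \sigma_k \sigma_l / 2}, takes its eigenvalues
#' \eqn{\lambda} and counts the effective number of parameters determined
#' by the data as \eqn{N_g = \sum_k \lambda_k/(\lambda_k + \alpha)}.
#' For uniform-prior fits the surrogate widths stored in the prior set
#' (one tenth of the bound width) provide the normalization scale.
#'
#' @param hessian symmetric Hessian of the (weighted) chi-square at the
#'   solution.
#' @param sigma prior widths, one per parameter.
#' @param alpha regularization weight at which to count (`1e-10`, the
#'   quenched value, makes `N_g` approach the full parameter count for a
#'   full-rank Hessian).
#' @return `N_g`, between 0 and the parameter count.
#' @export
ng_from_hessian <- function(hessian, sigma, alpha = 1e-10) {
  K <- nrow(hessian)
  if (length(sigma) != K) stop("sigma must match the Hessian dimension")
  B <- hessian * outer(sigma, sigma) / 2
  lam <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam < -1e-4 * max(abs(lam))))
    warning("negative Hessian eigenvalues: solution may be a saddle point")
  lam <- pmax(lam, 0)
  sum(lam / (lam + alpha))
}

#' Number of Shannon channels
#'
#' The sampling-theorem count of independent data channels in a measured
#' q window for a particle of maximum dimension `Dmax`:
#' \eqn{N_s = (q_{max} - q_{min}) D_{max} / \pi}.  Used as a fallback
#' information measure when BIFT cannot fit a dataset.
#'
#' @param qmin,qmax q window (1/Angstrom). @param Dmax maximum particle
#'   dimension (Angstrom).
#' @return `N_s` (not rounded).
#' @export
shannon_channels <- function(qmin, qmax, Dmax) {
  if (qmax <= qmin || qmin < 0 || Dmax <= 0)
    stop("need 0 <= qmin < qmax and Dmax > 0")
  (qmax - qmin) * Dmax / pi
}

#' Partition the degrees of freedom of a simultaneous fit across datasets
#'
#' Given each dataset's stand-alone upper-limit good-parameter count
#' `n_g,j` and the total `N_g` of the joint fit, distributes the total in
#' proportion, \eqn{N_{g,j} = n_{g,j} N_g / n_{all}} with
#' \eqn{n_{all} = \sum_j n_{g,j}}, so that the per-dataset values add up
#' to the total exactly.  Per-dataset degrees of freedom are then
#' \eqn{DOF_j = M_j - N_{g,j}} and reduced chi-squares
#' \eqn{\chi^2_j / DOF_j}.
#'
#' @param n_g per-dataset upper-limit good-parameter counts.
#' @param N_g total good parameters of the joint fit.
#' @param M per-dataset point counts.
#' @param chi2 per-dataset chi-squares (optional; reduced values are `NA`
#'   when missing).
#' @return A data frame with columns `M`, `n_g`, `N_g`, `dof`,
#'   `chi2`, `chi2_reduced`, one row per dataset plus bookkeeping in
#'   attributes `N_g_total` and `dof_total`.
#' @export
dof_partition <- function(n_g, N_g, M, chi2 = NULL) {
  if (any(n_g <= 0)) stop("all n_g must be > 0")
  n_all <- sum(n_g)
  if (N_g > n_all + 1e-9) stop("total N_g cannot exceed sum(n_g)")
  Ngj <- n_g * N_g / n_all
  if (any(Ngj >= M))
    stop("partitioned N_g reaches the dataset size: degenerate dataset")
  dof <- M - Ngj
  out <- data.frame(M = M, n_g = n_g, N_g = Ngj, dof = dof,
                    chi2 = if (is.null(chi2)) NA_real_ else chi2,
                    chi2_reduced = if (is.null(chi2)) NA_real_
                                   else chi2 / dof)
  attr(out, "N_g_total") <- N_g
  attr(out, "dof_total") <- sum(M) - N_g
  out
}
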