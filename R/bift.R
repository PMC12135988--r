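# Embedded Bayesian indirect Fourier transformation (BIFT): inversion of
# I(q) to the pair-distance distribution p(r) with a smoothness prior,
# non-negativity, and evidence-optimal selection of both the
# regularization weight alpha and the maximum dimension Dmax.  Its main
# consumer here is the information-based weighting scheme, via the number
# of good parameters N_g,BIFT.

# Lawson-Hanson style non-negative solve of A x = b (A symmetric p.d.),
# i.e. min x'Ax/2 - b'x s.t. x[nonneg] >= 0.  'free' indices are never
# constrained (background term); 'warm' optionally seeds the passive set.
.nnls_ne <- function(A, b, free = integer(0), warm = NULL,
                     max_pivot = 60) {
  n <- length(b)
  is_free <- seq_len(n) %in% free
  P <- if (is.null(warm)) rep(TRUE, n) else (warm | is_free)
  x <- numeric(n)
  tol <- 1e-10 * max(abs(b), 1)
  solveP <- function(P) {
    z <- numeric(n)
    App <- A[P, P, drop = FALSE]
    z[P] <- tryCatch(solve(App, b[P]), error = function(e)
      solve(App + diag(1e-10 * max(diag(App)), nrow(App)), b[P]))
    z
  }
  # standard Lawson-Hanson pivoting towards dual feasibility from the
  # current (x, P); single additions keep the feasibility guarantees
  polish <- function(x, P, budget) {
    conv <- FALSE
    for (outer in seq_len(budget)) {
      g <- b - A %*% x
      cand <- which(!P & g > max(tol, 1e-8 * max(abs(g))))
      if (!length(cand)) { conv <- TRUE; break }
      P[cand[which.max(g[cand])]] <- TRUE
      z <- solveP(P)
      guard <- 0
      while (any(bad <- (P & !is_free & z < 0)) && guard < n) {
        guard <- guard + 1
        frac <- x[bad] / (x[bad] - z[bad])
        step <- min(frac[is.finite(frac)], 1)
        x <- x + step * (z - x)
        P[P & !is_free & x <= tol] <- FALSE
        x[!P] <- 0
        z <- solveP(P)
      }
      x <- z
    }
    list(x = x, P = P, converged = conv ||
           !length(which(!P & (b - A %*% x) >
                           max(tol, 1e-8 * max(abs(b - A %*% x))))))
  }
  # fast path: settle from the full (or warm) support by dropping all
  # negative coordinates at once, then polish
  z <- solveP(P)
  for (it in seq_len(30)) {
    bad <- P & !is_free & z < 0
    if (!any(bad)) break
    P[bad] <- FALSE
    z <- solveP(P)
  }
  z[P & !is_free & z < 0] <- 0
  res <- polish(z, P, max_pivot)
  if (!res$converged) {
    # robust fallback: classic from-empty Lawson-Hanson
    P0 <- is_free
    x0 <- solveP(P0)
    res2 <- polish(x0, P0, 3 * n)
    obj <- function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x)
    if (obj(res2$x) < obj(res$x)) res <- res2
  }
  list(x = as.numeric(res$x), passive = res$P)
}

# Solve the regularized p(r) problem at fixed (Dmax, alpha) and return the
# pieces needed for the evidence and N_g.  'geom' caches the Dmax-level
# quantities (kernel, normal-equation blocks).
.bift_geometry <- function(curve, Dmax, n_r, fit_background) {
  q <- curve$q
  r <- Dmax * seq_len(n_r) / (n_r + 1)
  dr <- Dmax / (n_r + 1)
  qr <- outer(q, r)
  Tm <- 4 * pi * dr * sin(qr) / qr
  if (fit_background) Tm <- cbind(Tm, 1)
  Wh <- 1 / curve$sigma
  Tw <- Tm * Wh
  yw <- curve$I * Wh
  H <- crossprod(Tw)          # T' W T
  bvec <- crossprod(Tw, yw)[, 1]
  # second-difference smoothness precision with implicit zero endpoints
  n_tot <- ncol(Tm)
  L <- diag(-2, n_r)
  L[cbind(seq_len(n_r - 1), 2:n_r)] <- 1
  L[cbind(2:n_r, seq_len(n_r - 1))] <- 1
  C <- crossprod(L)
  Cfull <- matrix(0, n_tot, n_tot)
  Cfull[seq_len(n_r), seq_len(n_r)] <- C
  tau_bg <- 1e-10 * sum(Wh^2)  # vague prior keeping A invertible
  if (fit_background) Cfull[n_tot, n_tot] <- tau_bg
  # data-normalized smoothness scale: alpha = 1 balances prior and data
  # curvature, so the dimensionless alpha scan range is data-independent
  s_c <- mean(diag(H)[seq_len(n_r)]) / mean(diag(C))
  list(q = q, r = r, Tm = Tm, H = H, b = bvec, C = Cfull, n_r = n_r,
       n_tot = n_tot, free = if (fit_background) n_tot else integer(0),
       Wh = Wh, I = curve$I, Dmax = Dmax, bg = fit_background,
       tau_bg = tau_bg, s_c = s_c)
}

.bift_solve <- function(geom, alpha, warm = NULL, ng_also = FALSE,
                        max_pivot = 60, ref = NULL) {
  alpha <- alpha * geom$s_c  # dimensionless -> data scale
  A <- geom$H + alpha * geom$C
  if (geom$bg)  # bg prior precision is fixed, not alpha-scaled
    A[geom$n_tot, geom$n_tot] <- geom$H[geom$n_tot, geom$n_tot] +
      geom$C[geom$n_tot, geom$n_tot]
  sol <- .nnls_ne(A, geom$b, free = geom$free, warm = warm,
                  max_pivot = max_pivot)
  # safeguard: a feasible reference support from a neighbouring solve must
  # not beat the returned solution; if it does, re-polish from it
  if (!is.null(ref)) {
    obj <- function(x) 0.5 * sum(x * (A %*% x)) - sum(geom$b * x)
    if (obj(ref$x) < obj(sol$x) - 1e-8 * abs(obj(sol$x))) {
      sol2 <- .nnls_ne(A, geom$b, free = geom$free, warm = ref$passive,
                       max_pivot = max_pivot)
      if (obj(sol2$x) < obj(sol$x)) sol <- sol2
      if (obj(ref$x) < obj(sol$x)) sol <- list(x = ref$x,
                                               passive = ref$passive)
    }
  }
  x <- sol$x
  resid <- (geom$I - as.numeric(geom$Tm %*% x)) * geom$Wh
  chi2 <- sum(resid^2)
  S <- sum((x[seq_len(geom$n_r)] %*%
              geom$C[seq_len(geom$n_r), seq_len(geom$n_r)]) *
             x[seq_len(geom$n_r)])
  ch <- tryCatch(chol(A), error = function(e)
    chol(A + diag(1e-10 * max(diag(A)), nrow(A))))
  ld_A <- 2 * sum(log(diag(ch)))
  # evidence up to Dmax/alpha-independent constants:
  #   log E = -(chi2 + alpha S)/2 + (n_r/2) log alpha - log det(A)/2
  logE <- -(chi2 + alpha * S) / 2 + geom$n_r / 2 * log(alpha) - ld_A / 2
  ng <- if (ng_also) sum(chol2inv(ch) * geom$H) else NA_real_  # tr(A^-1 H)
  list(x = x, chi2 = chi2, S = S, ng = ng, logE = logE,
       passive = sol$passive)
}

# golden-section maximization of log-evidence over log10(alpha)
.bift_best_alpha <- function(geom, lo = -3, hi = 9, n_coarse = 5,
                             n_golden = 7) {
  grid <- seq(lo, hi, length.out = n_coarse)
  # sweep from the strongly regularized (smooth, well-conditioned) end
  # down, warm-starting the active set and carrying the best-chi2
  # solution as a safeguard reference
  warm <- NULL
  ref <- NULL
  keep_ref <- function(s) {
    if (is.null(ref) || s$chi2 < ref$chi2)
      ref <<- list(x = s$x, passive = s$passive, chi2 = s$chi2)
  }
  evals <- vector("list", n_coarse)
  for (i in rev(seq_len(n_coarse))) {
    evals[[i]] <- .bift_solve(geom, 10^grid[i], warm = warm,
                              max_pivot = 40, ref = ref)
    warm <- evals[[i]]$passive
    keep_ref(evals[[i]])
  }
  le <- vapply(evals, `[[`, numeric(1), "logE")
  i <- which.max(le)
  a <- grid[max(1, i - 1)]; b <- grid[min(n_coarse, i + 1)]
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- .bift_solve(geom, 10^x1, warm = warm, max_pivot = 40, ref = ref)
  keep_ref(f1)
  f2 <- .bift_solve(geom, 10^x2, warm = f1$passive, max_pivot = 40,
                    ref = ref)
  keep_ref(f2)
  for (it in seq_len(n_golden)) {
    if (f1$logE > f2$logE) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a)
      f1 <- .bift_solve(geom, 10^x1, warm = f2$passive, max_pivot = 40,
                        ref = ref)
      keep_ref(f1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a)
      f2 <- .bift_solve(geom, 10^x2, warm = f1$passive, max_pivot = 40,
                        ref = ref)
      keep_ref(f2)
    }
  }
  best <- if (f1$logE > f2$logE) list(la = x1, sol = f1)
          else list(la = x2, sol = f2)
  best$boundary <- best$la < lo + 0.15 || best$la > hi - 0.15
  best
}

#' Bayesian indirect Fourier transformation of a scattering curve
#'
#' Inverts \eqn{I(q) = \sum_j T_{ij} p_j} (sine-kernel transform
#' \eqn{T_{ij} = 4\pi \Delta r \sin(q_i r_j)/(q_i r_j)}, plus an optional
#' flat background term) for the pair-distance distribution `p(r)` on
#' `n_r` grid points, under a second-difference smoothness prior with
#' weight `alpha`, non-negativity of `p`, and implicit zeros at `r = 0`
#' and `r = Dmax`.  Both `alpha` and `Dmax` are selected by maximizing the
#' Laplace-approximation evidence (coarse grids refined by golden-section
#' search).  The number of good parameters,
#' \eqn{N_{g,BIFT} = \sum_k \lambda_k/(\lambda_k + \alpha)} over the
#' posterior eigenspectrum, quantifies the information content of the
#' curve and decreases as the noise level grows.
#'
#' @param curve a [sas_curve].
#' @param n_r number of `p(r)` grid points.
#' @param dmax_range search range for the maximum dimension (Angstrom).
#' @param n_dmax coarse Dmax grid size before golden refinement.
#' @param alpha_range log10 search limits for the smoothness weight.
#' @param fit_background include a flat background term (recommended for
#'   curves with a constant background).
#' @return An object of class `bift_result`: list with `r`, `pr`, `dmax`,
#'   `alpha`, `ng` (the `N_g,BIFT`), `chi2`, `chi2_reduced`, `background`,
#'   `evidence`, `M`, and `ok` (`FALSE` when the evidence maximum sat on
#'   the search boundary, in which case the boundary solution is returned
#'   and the caller may prefer [shannon_channels()]).
#' @examples
#' q <- make_qgrid(5e-3, 0.3, 60)
#' I <- coreshell_intensity(q, c(10, 30, 50, 50.0001), rho = c(1, 1, 1))
#' crv <- sas_curve(q, I, sigma = 0.01 * abs(I) + 1e-8)
#' @export
bift <- function(curve, n_r = 100, dmax_range = c(30, 300), n_dmax = 6,
                 alpha_range = c(-3, 9), fit_background = TRUE) {
  stopifnot(inherits(curve, "sas_curve"))
  eval_dmax <- function(D) {
    geom <- .bift_geometry(curve, D, n_r, fit_background)
    best <- .bift_best_alpha(geom, alpha_range[1], alpha_range[2])
    c(best, list(geom = geom))
  }
  Ds <- seq(dmax_range[1], dmax_range[2], length.out = n_dmax)
  cand <- lapply(Ds, eval_dmax)
  le <- vapply(cand, function(cc) cc$sol$logE, numeric(1))
  i <- which.max(le)
  # golden refinement of Dmax between the bracketing neighbours
  a <- Ds[max(1, i - 1)]; b <- Ds[min(n_dmax, i + 1)]
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  c1 <- eval_dmax(x1); c2 <- eval_dmax(x2)
  for (it in seq_len(4)) {
    if (c1$sol$logE > c2$sol$logE) {
      b <- x2; x2 <- x1; c2 <- c1; x1 <- b - gr * (b - a); c1 <- eval_dmax(x1)
    } else {
      a <- x1; x1 <- x2; c1 <- c2; x2 <- a + gr * (b - a); c2 <- eval_dmax(x2)
    }
  }
  pool <- c(cand, list(c1, c2))
  les <- vapply(pool, function(cc) cc$sol$logE, numeric(1))
  best <- pool[[which.max(les)]]
  boundary_d <- best$geom$Dmax <= Ds[1] + 1e-9 ||
    best$geom$Dmax >= Ds[n_dmax] - 1e-9
  if (boundary_d || best$boundary)
    warning("BIFT evidence maximum on the search boundary; ",
            "returning the boundary solution (consider shannon_channels)")
  sol <- .bift_solve(best$geom, 10^best$la, warm = best$sol$passive,
                     ng_also = TRUE)
  n_rr <- best$geom$n_r
  M <- nrow(curve)
  pr <- sol$x[seq_len(n_rr)]
  # size estimate: where p(r) has decayed to zero (the evidence-selected
  # grid envelope can extend beyond the particle without penalty)
  above <- which(pr > 1e-3 * max(pr))
  d_est <- if (length(above)) best$geom$r[max(above)] +
    best$geom$Dmax / (n_rr + 1) else best$geom$Dmax
  structure(list(
    r = best$geom$r, pr = pr,
    dmax = d_est, dmax_grid = best$geom$Dmax, alpha = 10^best$la,
    ng = sol$ng, chi2 = sol$chi2,
    chi2_reduced = sol$chi2 / (M - sol$ng),
    background = if (fit_background) sol$x[n_rr + 1] else 0,
    evidence = sol$logE, M = M,
    ok = !(boundary_d || best$boundary)),
    class = "bift_result")
}

#' @export
print.bift_result <- function(x, ...) {
  cat(sprintf(paste0("<bift: Dmax = %.1f A, alpha = %.3g, N_g = %.2f, ",
                     "chi2_r = %.3f (M = %d)%s>\n"),
              x$dmax, x$alpha, x$ng, x$chi2_reduced, x$M,
              if (x$ok) "" else " [boundary]"))
  invisible(x)
}

#' @export
plot.bift_result <- function(x, ...) {
  graphics::plot(x$r, x$pr, type = "l", xlab = "r (A)", ylab = "p(r)",
                 main = sprintf("p(r), Dmax = %.0f A", x$dmax), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
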