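# Replicated simulate-and-refit experiments: accuracy metrics
# (RMS deviation from truth and average relative deviation over the
# structural parameters), benchmark condition registry, bootstrap
# confidence intervals, and the error-misscaling / prior-quality sweeps.

#' RMS deviation of refined values from the true value
#'
#' \eqn{\Delta x = [\sum_r (x_r - x_{true})^2 / n_{rep}]^{1/2}}.  Because
#' the true value is known there are zero fitted degrees of freedom, so
#' the denominator is `n_rep`, not `n_rep - 1`.
#'
#' @param values numeric vector (one parameter) or matrix with one column
#'   per parameter and one row per replicate.
#' @param x_true true value(s).
#' @return Deviation(s), in parameter units.
#' @export
rms_deviation <- function(values, x_true) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (!nrow(values)) stop("no replicate values supplied")
  if (length(x_true) != ncol(values))
    stop("x_true must have one value per parameter")
  sqrt(colMeans((values - rep(x_true, each = nrow(values)))^2))
}

#' Average relative deviation of a parameter set, in percent
#'
#' The accuracy of a refinement condition condensed to one number: the
#' mean over the designated (structural) parameters of
#' \eqn{\Delta x_j / |x_{j,true}|}, expressed in percent.
#'
#' @param delta RMS deviations per parameter (see [rms_deviation()]).
#' @param x_true true values, none zero.
#' @return Percentage.
#' @export
avg_rel_deviation <- function(delta, x_true) {
  if (length(delta) != length(x_true)) stop("length mismatch")
  if (any(x_true == 0)) stop("relative deviation undefined for zero truth")
  mean(delta / abs(x_true)) * 100
}

#' Percentile bootstrap CI on the average relative deviation
#'
#' Resamples replicates with replacement and recomputes the average
#' relative deviation each time; the interval width shrinks roughly like
#' `1/sqrt(n_rep)`.
#'
#' @param values replicate-by-parameter matrix of refined values.
#' @param x_true true values. @param level confidence level.
#' @param n_boot bootstrap draws.
#' @return Length-2 interval (percent).
#' @export
bootstrap_ci <- function(values, x_true, level = 0.99, n_boot = 300) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  n <- nrow(values)
  if (n < 2) return(c(NA_real_, NA_real_))
  stat <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    avg_rel_deviation(rms_deviation(values[idx, , drop = FALSE], x_true),
                      x_true)
  }, numeric(1))
  unname(stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Define a core-multishell benchmark condition
#'
#' Describes one cell of the weighting-scheme benchmark grid: a paired
#' SAXS-like / SANS-like simulation of the core-multishell particle
#' (radii 10/30/50/70 Angstrom), with optional third core-contrast
#' dataset, hard-sphere structure factor, SANS resolution smearing, and
#' deliberate error mis-scaling.
#'
#' @param M_saxs,M_sans points in the SAXS-like / SANS-like datasets (0
#'   drops the dataset).
#' @param M_core points of an optional third SANS-like dataset in which
#'   only the core has contrast (0 = absent).
#' @param qmin,qmax common q window (1/Angstrom).
#' @param hs_eta optional hard-sphere volume fraction (structure factor
#'   used both to simulate and to fit; interaction radius `R_3`).
#' @param res_mult optional resolution multiplier: attaches a synthetic
#'   `sigma_q` column (times this factor) to the SANS-like dataset(s).
#' @param misscale_saxs,misscale_sans reported-error mis-scaling factors.
#' @param noise_factor variance inflation applied to every dataset.
#' @param priors radii prior fixture name (see [prior_fixtures()]).
#' @param label condition label.
#' @return An object of class `sas_condition`.
#' @export
cond_coreshell <- function(M_saxs = 400, M_sans = 50, M_core = 0,
                           qmin = 1e-3, qmax = 0.5, hs_eta = NULL,
                           res_mult = NULL, misscale_saxs = 1,
                           misscale_sans = 1, noise_factor = 1,
                           priors = "Uniform_5s", label = NULL) {
  ds <- list()
  if (M_saxs > 0)
    ds <- c(ds, list(list(role = "saxs", M = M_saxs,
                          noise = noise_spec("saxs",
                                             noise_factor = noise_factor,
                                             misscale = misscale_saxs),
                          res_mult = NULL)))
  if (M_sans > 0)
    ds <- c(ds, list(list(role = "sans", M = M_sans,
                          noise = noise_spec("sans",
                                             noise_factor = noise_factor,
                                             misscale = misscale_sans),
                          res_mult = res_mult)))
  if (M_core > 0)
    ds <- c(ds, list(list(role = "core", M = M_core,
                          noise = noise_spec("sans",
                                             noise_factor = noise_factor),
                          res_mult = res_mult)))
  if (!length(ds)) stop("condition needs at least one dataset")
  roles <- vapply(ds, `[[`, character(1), "role")
  model <- sas_model("coreshell3", hs_eta = hs_eta)
  structure(list(
    label = label %||% paste0("coreshell_",
                              paste(vapply(ds, `[[`, numeric(1), "M"),
                                    collapse = ":")),
    model = model, roles = roles, datasets = ds,
    truth = truth_coreshell(roles), qmin = qmin, qmax = qmax,
    priors_name = priors, priors = load_priors(priors, roles)),
    class = "sas_condition")
}

#' @export
print.sas_condition <- function(x, ...) {
  cat(sprintf("<sas_condition '%s': %s; priors %s>\n", x$label,
              paste(sprintf("%s(%d)", x$roles,
                            vapply(x$datasets, `[[`, numeric(1), "M")),
                    collapse = " + "), x$priors_name))
  invisible(x)
}

# deterministic per-replicate seed below 2^31
.rep_seed <- function(seed, r, salt = 0L)
  (as.integer(seed) %% 65011L) * 33013L + salt * 257L + r

# simulate all datasets of a condition for replicate r
.simulate_condition <- function(cond, seed_r) {
  set.seed(.rep_seed(seed_r, 0L))
  lapply(seq_along(cond$datasets), function(j) {
    d <- cond$datasets[[j]]
    q <- make_qgrid(cond$qmin, cond$qmax, d$M)
    sq <- if (!is.null(d$res_mult))
      synth_sigma_q(q, multiplier = d$res_mult) else NULL
    simulate_dataset(cond$model, cond$truth, j, q, d$noise, sigma_q = sq,
                     label = toupper(d$role))
  })
}

# single-dataset sub-problem of a condition: dataset j refined alone
.single_setup <- function(cond, j) {
  role <- cond$roles[j]
  list(truth = truth_coreshell(role),
       priors = load_priors(cond$priors_name, role))
}

#' Run a replicated simulate-and-refit benchmark condition
#'
#' For each replicate, simulates fresh datasets from the condition's true
#' model and refines the model back with each requested fitting mode; the
#' refined structural parameters are collected and condensed into the RMS
#' deviation per parameter and the average relative deviation (percent),
#' with a percentile-bootstrap confidence interval.  All modes see the
#' same simulated data within a replicate.  Deterministic given `seed`.
#'
#' @param cond a [cond_coreshell()] condition.
#' @param modes any of `"naive"`, `"reduced"`, `"information"` (joint
#'   fits) and dataset roles (`"saxs"`, `"sans"`, `"core"`: fit that
#'   dataset alone).
#' @param n_rep number of replicates.
#' @param seed base seed; replicate r uses a seed derived from
#'   `seed`, `r` and the condition label.
#' @param ng_per_replicate recompute the BIFT information weights for
#'   every replicate (default); `FALSE` reuses the first replicate's.
#' @param keep_values keep the full replicate-by-parameter matrices.
#' @return An object of class `sas_eval`: per-mode list with `delta`
#'   (RMS deviations), `avg_rel` (percent), `ci` (99 percent bootstrap),
#'   `values` (if kept), plus failure counts.
#' @export
run_condition <- function(cond, modes = "naive", n_rep = 100, seed = 1,
                          ng_per_replicate = TRUE, keep_values = TRUE) {
  stopifnot(inherits(cond, "sas_condition"))
  if (n_rep < 1) stop("n_rep must be >= 1")
  joint_modes <- intersect(modes, c("naive", "reduced", "information"))
  single_modes <- setdiff(modes, joint_modes)
  bad <- setdiff(single_modes, cond$roles)
  if (length(bad)) stop("unknown mode(s): ", paste(bad, collapse = ", "))
  singles <- lapply(single_modes, function(role)
    .single_setup(cond, match(role, cond$roles)))
  names(singles) <- single_modes
  sp <- cond$model$structural
  salt <- sum(utf8ToInt(cond$label)) %% 997L
  est <- lapply(stats::setNames(modes, modes), function(m)
    matrix(NA_real_, n_rep, length(sp), dimnames = list(NULL, sp)))
  n_fail <- stats::setNames(integer(length(modes)), modes)
  ng_cache <- NULL
  for (r in seq_len(n_rep)) {
    curves <- .simulate_condition(cond, .rep_seed(seed, r, salt))
    ng <- NULL
    if ("information" %in% modes) {
      if (ng_per_replicate || is.null(ng_cache)) {
        ng <- vapply(curves, function(cc)
          suppressWarnings(bift(cc)$ng), numeric(1))
        if (!ng_per_replicate) ng_cache <- ng
      } else ng <- ng_cache
    }
    for (m in modes) {
      fit <- tryCatch({
        if (m %in% joint_modes)
          corefit(curves, cond$model, cond$priors, scheme = m,
                  ng_bift = if (m == "information") ng else NULL)
        else {
          j <- match(m, cond$roles)
          corefit(curves[[j]], cond$model, singles[[m]]$priors)
        }
      }, error = function(e) NULL)
      if (is.null(fit)) n_fail[m] <- n_fail[m] + 1L
      else est[[m]][r, ] <- fit$coefficients[sp]
    }
  }
  truth_sp <- cond$truth[sp]
  res <- lapply(modes, function(m) {
    vals <- est[[m]][stats::complete.cases(est[[m]]), , drop = FALSE]
    delta <- rms_deviation(vals, truth_sp)
    list(mode = m,
         delta = stats::setNames(delta, sp),
         avg_rel = avg_rel_deviation(delta, truth_sp),
         ci = bootstrap_ci(vals, truth_sp),
         n_used = nrow(vals),
         values = if (keep_values) vals else NULL)
  })
  names(res) <- modes
  flagged <- n_fail > 0.05 * n_rep
  if (any(flagged))
    warning("more than 5% fit failures in mode(s): ",
            paste(modes[flagged], collapse = ", "))
  structure(list(condition = cond$label, truth = truth_sp, n_rep = n_rep,
                 results = res, n_fail = n_fail, seed = seed),
            class = "sas_eval")
}

#' @export
print.sas_eval <- function(x, ...) {
  cat(sprintf("<sas_eval '%s', n_rep = %d>\n", x$condition, x$n_rep))
  for (m in names(x$results)) {
    r <- x$results[[m]]
    cat(sprintf("  %-12s avg rel dev = %5.2f%%  (99%% CI [%.2f, %.2f], n = %d)\n",
                m, r$avg_rel, r$ci[1], r$ci[2], r$n_used))
  }
  invisible(x)
}

#' Error mis-scaling sweep
#'
#' Re-runs a benchmark condition with the reported errors of one dataset
#' multiplied by each factor after simulation (intensity fluctuations
#' unchanged), quantifying how over- or under-estimated errors degrade
#' the refined radii.
#'
#' @param factors positive mis-scaling factors (1 = correct errors).
#' @param which_role dataset whose reported errors are mis-scaled.
#' @param n_rep,seed replication settings.
#' @param modes fitting modes (default naive joint fit).
#' @param ... passed to [cond_coreshell()].
#' @return A data frame: one row per factor and mode, with per-radius
#'   RMS deviations and the average relative deviation.
#' @export
misscale_sweep <- function(factors = c(0.1, 1, 10), which_role = "sans",
                           n_rep = 100, seed = 1, modes = "naive", ...) {
  out <- list()
  for (f in factors) {
    cond <- if (which_role == "sans")
      cond_coreshell(misscale_sans = f, ...)
    else cond_coreshell(misscale_saxs = f, ...)
    cond$label <- paste0(cond$label, "_m", f)
    ev <- run_condition(cond, modes = modes, n_rep = n_rep, seed = seed,
                        keep_values = FALSE)
    for (m in modes) {
      r <- ev$results[[m]]
      out[[length(out) + 1L]] <-
        data.frame(factor = f, mode = m, t(r$delta),
                   avg_rel = r$avg_rel, check.names = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Prior-quality sweep
#'
#' Fits the same simulated replicates with a series of prior fixtures
#' (Gaussian priors via the evidence-weighted alpha scan, uniform priors
#' via the quenched single fit) and reports the per-radius RMS deviations
#' for each, quantifying how much informative priors improve the refined
#' structural parameters.
#'
#' @param prior_names fixture names (see [prior_fixtures()]).
#' @param n_rep,seed replication settings.
#' @param M_saxs,M_sans dataset sizes.
#' @return A data frame: one row per fixture with per-radius RMS
#'   deviations and the average relative deviation.
#' @export
prior_sweep <- function(prior_names = c("Uniform_5s", "Gaussian_best"),
                        n_rep = 50, seed = 1, M_saxs = 400, M_sans = 50) {
  cond <- cond_coreshell(M_saxs = M_saxs, M_sans = M_sans)
  sp <- cond$model$structural
  salt <- sum(utf8ToInt(cond$label)) %% 997L
  priors <- lapply(prior_names, load_priors, roles = cond$roles)
  est <- lapply(stats::setNames(prior_names, prior_names), function(p)
    matrix(NA_real_, n_rep, length(sp), dimnames = list(NULL, sp)))
  for (r in seq_len(n_rep)) {
    curves <- .simulate_condition(cond, .rep_seed(seed, r, salt))
    for (i in seq_along(prior_names)) {
      fit <- tryCatch(
        corefit(curves, cond$model, priors[[i]], scheme = "naive"),
        error = function(e) NULL)
      if (!is.null(fit)) est[[i]][r, ] <- fit$coefficients[sp]
    }
  }
  truth_sp <- cond$truth[sp]
  do.call(rbind, lapply(prior_names, function(p) {
    vals <- est[[p]][stats::complete.cases(est[[p]]), , drop = FALSE]
    delta <- rms_deviation(vals, truth_sp)
    data.frame(prior = p, t(delta),
               avg_rel = avg_rel_deviation(delta, truth_sp),
               n_used = nrow(vals), check.names = FALSE)
  }))
}
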