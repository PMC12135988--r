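# Run configuration (YAML) and the umbrella command-line interface.
# The CLI is a thin layer over the exported functions; the R API is the
# primary interface.

#' Read a fit configuration file
#'
#' YAML configuration mirroring a typical refinement input file:
#' \preformatted{
#' model: coreshell3
#' scheme: naive            # naive | reduced | information
#' priors: Gaussian_best    # fixture name, or a list of parameter rows
#' datasets:
#'   - {path: saxs.dat, role: saxs}
#'   - {path: sans.dat, role: sans}
#' alpha_range: [0.01, 100]
#' seed: 1
#' }
#' Priors may alternatively be given inline as a list of rows with
#' `par`, `kind`, `mu`, `sigma` and optional `lower`/`upper`.
#'
#' @param path YAML file path.
#' @return A named list (class `sas_config`) with `model`, `curves`,
#'   `priors`, `scheme`, `alpha_range`, `seed`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model) || is.null(cfg$datasets))
    stop("config must name a model and at least one dataset")
  base <- dirname(normalizePath(path))
  curves <- lapply(cfg$datasets, function(d) {
    p <- d$path
    if (!file.exists(p)) p <- file.path(base, d$path)
    read_sas(p, label = d$label %||% d$role %||% basename(d$path))
  })
  roles <- vapply(cfg$datasets, function(d) d$role %||% "saxs",
                  character(1))
  priors <- if (is.character(cfg$priors))
    load_priors(cfg$priors, roles = roles)
  else {
    rows <- cfg$priors
    prior_set(par = vapply(rows, `[[`, character(1), "par"),
              kind = vapply(rows, function(r) r$kind %||% "gaussian",
                            character(1)),
              mu = vapply(rows, `[[`, numeric(1), "mu"),
              sigma = vapply(rows, `[[`, numeric(1), "sigma"),
              lower = vapply(rows, function(r) r$lower %||% NA_real_,
                             numeric(1)),
              upper = vapply(rows, function(r) r$upper %||% NA_real_,
                             numeric(1)))
  }
  structure(list(model = sas_model(cfg$model), curves = curves,
                 roles = roles, priors = priors,
                 scheme = cfg$scheme %||% "naive",
                 alpha_range = as.numeric(cfg$alpha_range %||%
                                            c(1e-2, 1e2)),
                 seed = cfg$seed %||% 1L),
            class = "sas_config")
}

# minimal flag parser: --key value pairs plus positional arguments
.parse_flags <- function(args) {
  flags <- list(); pos <- character(0); i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        flags[[key]] <- args[i + 1]; i <- i + 2
      } else { flags[[key]] <- TRUE; i <- i + 1 }
    } else { pos <- c(pos, a); i <- i + 1 }
  }
  list(flags = flags, pos = pos)
}

.cli_usage <- function() {
  cat("usage: corefit <simulate|fit|bift|evaluate> [options]\n",
      "  simulate --model coreshell3 --preset saxs400|sans50 [--M n]\n",
      "           [--role saxs|sans|core] [--qmin q] [--qmax q]\n",
      "           --seed n -o out.dat\n",
      "  fit      --config run.yaml [--scheme naive|reduced|information]\n",
      "           [--uniform-priors] [--out dir]\n",
      "  bift     data.dat [--nr n] [--dmax-min d] [--dmax-max d]\n",
      "           --output pr.dat\n",
      "  evaluate --grid table1 [--nrep n] [--seed n]\n",
      "           [--schemes naive,reduced] --out results.csv\n", sep = "")
}

.cli_simulate <- function(fl) {
  preset <- fl$preset %||% "saxs400"
  role <- fl$role %||% if (grepl("^sans", preset)) "sans" else "saxs"
  M <- as.integer(fl$M %||% sub("^[a-z]+", "", preset))
  model <- sas_model(fl$model %||% "coreshell3")
  roles <- c("saxs", "sans")
  theta <- truth_coreshell(roles)
  j <- match(role, roles)
  if (role == "core") { theta <- truth_coreshell(c("saxs", "core")); j <- 2 }
  q <- make_qgrid(as.numeric(fl$qmin %||% 1e-3),
                  as.numeric(fl$qmax %||% 0.5), M)
  crv <- simulate_dataset(model, theta, j, q,
                          noise_spec(if (role == "saxs") "saxs" else "sans"),
                          seed = as.integer(fl$seed %||% 1),
                          label = toupper(role))
  write_sas(crv, fl$o %||% fl$out %||% "simulated.dat",
            header = c(paste("model:", model$name),
                       paste("role:", role),
                       paste("seed:", fl$seed %||% 1),
                       paste("truth:", paste(sprintf("%s=%g", names(theta),
                                                     theta),
                                             collapse = " "))))
  message("wrote ", fl$o %||% fl$out %||% "simulated.dat", " (", M,
          " points)")
  0L
}

.cli_fit <- function(fl) {
  cfg <- read_config(fl$config)
  if (!is.null(fl$scheme)) cfg$scheme <- fl$scheme
  priors <- cfg$priors
  if (isTRUE(fl[["uniform-priors"]])) priors$kind <- "uniform"
  set.seed(cfg$seed)
  fit <- corefit(cfg$curves, cfg$model, priors, scheme = cfg$scheme,
                 alpha_range = cfg$alpha_range)
  out_dir <- fl$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sm <- summary(fit)
  rep_path <- file.path(out_dir, "fit_report.txt")
  n_sink <- sink.number()
  sink(rep_path)
  on.exit(while (sink.number() > n_sink) sink(), add = TRUE)
  cat("corefit report\nseed:", cfg$seed, "\nscheme:", cfg$scheme, "\n\n")
  print(sm)
  sink()
  for (j in seq_along(cfg$curves)) {
    fitted_curve <- sas_curve(cfg$curves[[j]]$q, predict(fit, j),
                              cfg$curves[[j]]$sigma,
                              label = paste0(curve_label(cfg$curves[[j]]),
                                             "_fit"))
    write_sas(fitted_curve,
              file.path(out_dir, sprintf("fit_dataset%d.dat", j)))
  }
  message("wrote ", rep_path)
  print(fit)
  0L
}

.cli_bift <- function(fl, pos) {
  if (!length(pos)) { .cli_usage(); return(2L) }
  crv <- read_sas(pos[1])
  res <- bift(crv, n_r = as.integer(fl$nr %||% 100),
              dmax_range = c(as.numeric(fl[["dmax-min"]] %||% 30),
                             as.numeric(fl[["dmax-max"]] %||% 300)))
  out <- fl$output %||% "pr.dat"
  writeLines(c(sprintf("# BIFT of %s", pos[1]),
               sprintf("# alpha = %g  Dmax = %.2f A  N_g = %.3f  chi2_r = %.4f",
                       res$alpha, res$dmax, res$ng, res$chi2_reduced),
               "# columns: r p(r)",
               sprintf("%.6e %.6e", res$r, res$pr)), out)
  message("wrote ", out)
  print(res)
  0L
}

.cli_evaluate <- function(fl) {
  n_rep <- as.integer(fl$nrep %||% 10)
  seed <- as.integer(fl$seed %||% 1)
  schemes <- strsplit(fl$schemes %||% "naive,reduced,information",
                      ",")[[1]]
  grid <- fl$grid %||% "table1"
  conds <- switch(grid,
    table1 = list(cond_coreshell(300, 300), cond_coreshell(400, 50),
                  cond_coreshell(900, 50), cond_coreshell(2000, 50),
                  cond_coreshell(400, 50, M_core = 50),
                  cond_coreshell(400, 50, hs_eta = 0.2)),
    stop("unknown grid: ", grid))
  rows <- lapply(conds, function(cond) {
    ev <- run_condition(cond, modes = c(schemes, "sans", "saxs"),
                        n_rep = n_rep, seed = seed, keep_values = FALSE)
    vals <- vapply(ev$results, `[[`, numeric(1), "avg_rel")
    data.frame(condition = cond$label, t(vals), check.names = FALSE)
  })
  out <- fl$out %||% "results.csv"
  utils::write.csv(do.call(rbind, rows), out, row.names = FALSE)
  message("wrote ", out)
  0L
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `fit`, `bift` and `evaluate` subcommands
#' (see the `inst/exec/corefit` script).  Returns the exit status rather
#' than calling `quit()`, so it is also callable in-process.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status (0 on success, 2 on usage errors).
#' @export
sas_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { .cli_usage(); return(2L) }
  cmd <- args[1]
  parsed <- .parse_flags(args[-1])
  fl <- parsed$flags
  status <- tryCatch(switch(cmd,
    simulate = .cli_simulate(fl),
    fit = .cli_fit(fl),
    bift = .cli_bift(fl, parsed$pos),
    evaluate = .cli_evaluate(fl),
    { .cli_usage(); 2L }),
    error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
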