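# Named model registry.  A sas_model bundles the parameter layout for a
# multi-dataset refinement (shared structural parameters plus per-dataset
# nuisance parameters) with an intensity evaluator; corefit(), the
# simulator and the evaluation framework all consume the same object.

#' Construct a scattering model for (co-)refinement
#'
#' Returns a model object from the registry.  Available models:
#' \describe{
#'   \item{`coreshell3`}{Core + three concentric shells (sphere geometry).
#'     Shared parameters `R_c, R_1, R_2, R_3` (Angstrom); per dataset
#'     `rho1, rho2, rho3` (shell contrasts relative to the core), scale `a`
#'     (1/cm) and background `b` (1/cm).  Optionally multiplied by a
#'     Percus-Yevick hard-sphere structure factor.}
#'   \item{`stackedcyl3`}{Three coaxial stacked cylinders.  Shared
#'     `R, L_1, L_2, L_3` (Angstrom); per dataset `rho2, rho3` (contrasts
#'     relative to the first cylinder), `a`, `b`.}
#'   \item{`mixture`}{Linear mixture of two tabulated component curves per
#'     dataset; shared fraction `f1`, per dataset scale `s`.  Requires
#'     `components`.}
#' }
#'
#' @param name model name.
#' @param hs_eta optional hard-sphere volume fraction; if given, a
#'   Percus-Yevick structure factor multiplies the form factor
#'   (`coreshell3` only).
#' @param hs_R optional hard-sphere radius (Angstrom); default is the
#'   current outermost radius `R_3` during fitting.
#' @param components for `mixture`: a list with one entry per dataset, each
#'   a list of two component [sas_curve]s (or `data.frame`s with `q`, `I`)
#'   tabulated on that dataset's q grid.
#' @param n_nodes quadrature nodes for the stacked-cylinder orientational
#'   average.
#' @param fn for `name = "custom"`: an evaluator
#'   `function(q, shared, ds, j)` returning intensities, where `shared`
#'   and `ds` are the named shared / per-dataset parameter vectors.
#' @param shared,per_dataset,structural for `name = "custom"`: the
#'   parameter layout (names of shared parameters, per-dataset parameter
#'   basenames, and the structural subset used by accuracy metrics).
#' @return An object of class `sas_model`.
#' @examples
#' m <- sas_model("coreshell3")
#' model_par_names(m, n_datasets = 2)
#' @export
sas_model <- function(name = c("coreshell3", "stackedcyl3", "mixture",
                               "custom"),
                      hs_eta = NULL, hs_R = NULL, components = NULL,
                      n_nodes = 128, fn = NULL, shared = NULL,
                      per_dataset = character(0), structural = shared) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(fn) || is.null(shared))
      stop("custom models need 'fn' and 'shared'")
    return(structure(list(name = "custom", shared = shared,
                          per_dataset = per_dataset,
                          structural = structural, units = NULL, fn = fn),
                     class = "sas_model"))
  }
  m <- switch(name,
    coreshell3 = list(
      name = "coreshell3",
      shared = c("R_c", "R_1", "R_2", "R_3"),
      per_dataset = c("rho1", "rho2", "rho3", "a", "b"),
      structural = c("R_c", "R_1", "R_2", "R_3"),
      units = c(R_c = "A", R_1 = "A", R_2 = "A", R_3 = "A", rho1 = "",
                rho2 = "", rho3 = "", a = "1/cm", b = "1/cm"),
      hs_eta = hs_eta, hs_R = hs_R),
    stackedcyl3 = list(
      name = "stackedcyl3",
      shared = c("R", "L_1", "L_2", "L_3"),
      per_dataset = c("rho2", "rho3", "a", "b"),
      structural = c("R", "L_1", "L_2", "L_3"),
      units = c(R = "A", L_1 = "A", L_2 = "A", L_3 = "A", rho2 = "",
                rho3 = "", a = "1/cm", b = "1/cm"),
      n_nodes = n_nodes),
    mixture = {
      if (is.null(components)) stop("mixture model requires 'components'")
      list(
        name = "mixture",
        shared = "f1",
        per_dataset = "s",
        structural = "f1",
        units = c(f1 = "", s = ""),
        components = components)
    })
  structure(m, class = "sas_model")
}

#' @export
print.sas_model <- function(x, ...) {
  cat(sprintf("<sas_model '%s': shared [%s]; per dataset [%s]>\n", x$name,
              paste(x$shared, collapse = ", "),
              paste(x$per_dataset, collapse = ", ")))
  invisible(x)
}

#' List the models in the registry
#' @return Character vector of model names.
#' @export
list_models <- function() c("coreshell3", "stackedcyl3", "mixture")

#' Parameter names of a model for a given number of datasets
#'
#' Shared parameters come first, then each dataset's nuisance parameters
#' suffixed `.j`.
#'
#' @param model a [sas_model].
#' @param n_datasets number of simultaneously fitted datasets.
#' @return Character vector of parameter names (the layout of the
#'   coefficient vector of a [corefit] fit).
#' @export
model_par_names <- function(model, n_datasets) {
  if (!length(model$per_dataset)) return(model$shared)
  c(model$shared,
    unlist(lapply(seq_len(n_datasets), function(j)
      paste(model$per_dataset, j, sep = "."))))
}

# split a full named parameter vector into shared + per-dataset pieces
.split_pars <- function(model, theta, j) {
  shared <- theta[model$shared]
  ds <- theta[paste(model$per_dataset, j, sep = ".")]
  names(ds) <- model$per_dataset
  list(shared = shared, ds = ds)
}

# Evaluate dataset j of a joint model at the full parameter vector theta.
# validate = FALSE tolerates unordered intermediate iterates during fitting.
model_intensity <- function(model, q, theta, j = 1, validate = FALSE) {
  p <- .split_pars(model, theta, j)
  sh <- p$shared; ds <- p$ds
  if (!is.null(model$fn)) return(model$fn(q, sh, ds, j))
  switch(model$name,
    coreshell3 = {
      sq <- NULL
      if (!is.null(model$hs_eta) && model$hs_eta > 0) {
        Rhs <- if (is.null(model$hs_R)) abs(sh[["R_3"]]) else model$hs_R
        sq <- hardsphere_sq(q, Rhs, model$hs_eta)
      }
      coreshell_intensity(q, radii = unname(sh),
                          rho = unname(ds[c("rho1", "rho2", "rho3")]),
                          a = ds[["a"]], b = ds[["b"]], sq = sq,
                          validate = validate)
    },
    stackedcyl3 =
      stacked_cylinder_intensity(q, R = sh[["R"]],
                                 L = unname(sh[c("L_1", "L_2", "L_3")]),
                                 rho = c(1, unname(ds[c("rho2", "rho3")])),
                                 a = ds[["a"]], b = ds[["b"]],
                                 n_nodes = model$n_nodes %||% 128,
                                 validate = validate),
    mixture = {
      comp <- model$components[[j]]
      if (max(abs(comp[[1]]$q - q)) > 1e-12 * max(q))
        stop("component curves not tabulated on the dataset q grid")
      mixture_intensity(q, comp[[1]]$I, comp[[2]]$I,
                        f1 = sh[["f1"]], s = ds[["s"]])
    },
    stop("unknown model: ", model$name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
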