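#' Scattering curve container
#'
#' A `sas_curve` holds one reduced small-angle scattering dataset: the
#' momentum-transfer grid `q` (1/Angstrom), intensities `I` (1/cm),
#' point-wise standard errors `sigma` (1/cm) and, optionally, per-point
#' q-resolution widths `sigma_q` (1/Angstrom) used for Gaussian smearing.
#' It is a plain `data.frame` subclass, so all usual column access works.
#'
#' @param q numeric, strictly increasing, positive momentum transfer.
#' @param I numeric intensities, same length as `q`.
#' @param sigma positive numeric standard errors, same length as `q`.
#' @param sigma_q optional non-negative q-resolution widths, same length.
#' @param label short dataset label (used in printing and fit reports).
#'
#' @return An object of class `sas_curve` (and `data.frame`).
#' @examples
#' crv <- sas_curve(q = c(0.01, 0.02, 0.03), I = c(10, 9, 7),
#'                  sigma = c(0.5, 0.4, 0.4), label = "demo")
#' nrow(crv)
#' @export
sas_curve <- function(q, I, sigma, sigma_q = NULL, label = "data") {
  q <- as.numeric(q); I <- as.numeric(I); sigma <- as.numeric(sigma)
  if (length(q) != length(I) || length(q) != length(sigma))
    stop("q, I and sigma must have the same length")
  if (any(!is.finite(q)) || any(diff(q) <= 0))
    stop("q must be finite and strictly increasing")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all sigma must be finite and > 0")
  df <- data.frame(q = q, I = I, sigma = sigma)
  if (!is.null(sigma_q)) {
    sigma_q <- as.numeric(sigma_q)
    if (length(sigma_q) != length(q))
      stop("sigma_q must have the same length as q")
    if (any(sigma_q < 0)) stop("sigma_q must be >= 0")
    df$sigma_q <- sigma_q
  }
  structure(df, label = as.character(label)[1],
            class = c("sas_curve", "data.frame"))
}

#' @export
print.sas_curve <- function(x, ...) {
  cat(sprintf("<sas_curve '%s': %d points, q in [%g, %g] 1/A%s>\n",
              attr(x, "label"), nrow(x), min(x$q), max(x$q),
              if (!is.null(x$sigma_q)) ", with q-resolution column" else ""))
  invisible(x)
}

curve_label <- function(x) {
  lb <- attr(x, "label")
  if (is.null(lb)) "data" else lb
}

#' Read a scattering curve from a whitespace-delimited ASCII file
#'
#' Parses the de facto reduced-SAS text format: whitespace-separated numeric
#' columns `q I sigma [sigma_q]`, with `#`-comment lines, free-text header
#' lines and blank lines skipped.  Rows with `sigma <= 0` are dropped (a
#' message reports how many).
#'
#' @param path file path.
#' @param label dataset label; defaults to the file name.
#' @return A [sas_curve].
#' @seealso [write_sas()]
#' @export
read_sas <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- nzchar(trimws(lines))
  rows <- list(); bad <- integer(0)
  for (i in which(keep)) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) >= 3 && !anyNA(vals[1:3])) {
      rows[[length(rows) + 1L]] <- vals[1:min(4, length(vals))]
    } else bad <- c(bad, i)
  }
  if (!length(rows))
    stop("no numeric data rows (>= 3 columns) found in ", path,
         if (length(bad)) paste0("; offending lines: ",
                                 paste(utils::head(bad, 5), collapse = ", ")))
  ncol_min <- min(lengths(rows))
  m <- do.call(rbind, lapply(rows, function(r) r[seq_len(ncol_min)]))
  ok <- m[, 3] > 0
  if (any(!ok)) message(sum(!ok), " rows with sigma <= 0 dropped from ", path)
  m <- m[ok, , drop = FALSE]
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  sas_curve(q = m[, 1], I = m[, 2], sigma = m[, 3],
            sigma_q = if (ncol_min >= 4) m[, 4] else NULL,
            label = if (is.null(label)) basename(path) else label)
}

#' Write a scattering curve as 3- or 4-column ASCII
#'
#' Writes `q I sigma [sigma_q]` in full double precision, preceded by
#' `#`-comment header lines (label plus any extra header text supplied).
#'
#' @param curve a [sas_curve].
#' @param path output file path.
#' @param header optional character vector of extra header lines (written
#'   with a leading `# `), e.g. truth parameters or the noise settings used
#'   for a simulated curve.
#' @return `path`, invisibly.
#' @export
write_sas <- function(curve, path, header = character(0)) {
  stopifnot(inherits(curve, "sas_curve"))
  hdr <- c(sprintf("# %s", c(paste0("label: ", curve_label(curve)), header)),
           if (!is.null(curve$sigma_q)) "# columns: q I sigma sigma_q"
           else "# columns: q I sigma")
  cols <- c("q", "I", "sigma", if (!is.null(curve$sigma_q)) "sigma_q")
  body <- do.call(paste, c(lapply(cols, function(cn)
    formatC(curve[[cn]], format = "e", digits = 17)), sep = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
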