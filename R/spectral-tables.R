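#' Wavelength-sampled spectral tables
#'
#' A `spectral_table` holds one or more functions of wavelength sampled on a
#' strictly increasing grid: either the relative spectral power of an
#' illuminant (one column) or a triple of colour-matching functions
#' (three columns).
#'
#' @param wavelength numeric vector of wavelengths in nm, strictly increasing.
#' @param values numeric vector or matrix with one row per wavelength; one
#'   column for an illuminant, three for colour-matching functions.
#' @param kind `"illuminant"` or `"cmf"`.
#' @return An object of class `spectral_table` with fields `wavelength`,
#'   `values` (matrix) and `kind`.
#' @export
spectral_table <- function(wavelength, values, kind = c("illuminant", "cmf")) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  values <- as.matrix(values)
  if (any(!is.finite(wavelength)) || any(!is.finite(values)))
    stop("spectral table contains non-finite entries", call. = FALSE)
  if (length(wavelength) < 2L || any(diff(wavelength) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (nrow(values) != length(wavelength))
    stop("values must have one row per wavelength", call. = FALSE)
  ncol_want <- if (kind == "illuminant") 1L else 3L
  if (ncol(values) != ncol_want)
    stop(sprintf("a %s table needs %d value column(s), got %d",
                 kind, ncol_want, ncol(values)), call. = FALSE)
  if (kind == "illuminant" && any(values < 0))
    stop("illuminant power must be non-negative", call. = FALSE)
  structure(list(wavelength = wavelength, values = values, kind = kind),
            class = "spectral_table")
}

#' @export
print.spectral_table <- function(x, ...) {
  cat(sprintf("<spectral_table: %s, %d samples, %.5g-%.5g nm>\n",
              x$kind, length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Read a CIE-style spectral table from CSV and resample it
#'
#' Reads a CSV with a wavelength column followed by one (illuminant) or three
#' (colour-matching function) value columns, then resamples the values onto a
#' uniform working grid. The vendored CIE tables are 10-nm tabulations, so the
#' default interpolation is a cubic (FMM) spline, clamped at zero for
#' colour-matching functions; `"linear"` interpolation is also available.
#'
#' @param path path to a CSV file.
#' @param kind `"illuminant"` or `"cmf"`.
#' @param grid target wavelength grid in nm (default 380-700 at 1 nm).
#' @param interp `"spline"` (default) or `"linear"`.
#' @return A [spectral_table()] on `grid`.
#' @examples
#' d65 <- load_spectral_table(cie_path("illuminant_d65.csv"), "illuminant")
#' d65$values[d65$wavelength == 560, ]  # D65 is normalized to 100 at 560 nm
#' @export
load_spectral_table <- function(path, kind = c("illuminant", "cmf"),
                                grid = seq(380, 700, by = 1),
                                interp = c("spline", "linear")) {
  kind <- match.arg(kind)
  interp <- match.arg(interp)
  raw <- utils::read.csv(path)
  ncol_want <- if (kind == "illuminant") 1L else 3L
  if (ncol(raw) < ncol_want + 1L)
    stop(sprintf("'%s': expected a wavelength column plus %d value column(s)",
                 path, ncol_want), call. = FALSE)
  raw <- raw[, seq_len(ncol_want + 1L), drop = FALSE]
  if (!all(vapply(raw, is.numeric, logical(1))))
    stop(sprintf("'%s': non-numeric columns", path), call. = FALSE)
  wl <- raw[[1L]]
  if (length(wl) < 2L || any(diff(wl) <= 0))
    stop(sprintf("'%s': wavelengths must be strictly increasing", path),
         call. = FALSE)
  if (min(grid) < min(wl) || max(grid) > max(wl))
    stop(sprintf("'%s': table covers %g-%g nm, cannot resample to %g-%g nm",
                 path, min(wl), max(wl), min(grid), max(grid)), call. = FALSE)
  vals <- vapply(seq_len(ncol_want), function(j) {
    y <- raw[[j + 1L]]
    out <- if (interp == "spline")
      stats::spline(wl, y, xout = grid, method = "fmm")$y
    else
      stats::approx(wl, y, xout = grid)$y
    # interpolation must not manufacture negative power or sensitivity
    pmax(out, 0)
  }, numeric(length(grid)))
  spectral_table(grid, vals, kind)
}

#' Path to a vendored CIE reference table
#'
#' The package ships the CIE illuminant D65 relative spectral power
#' distribution (`"illuminant_d65.csv"`, normalized to 100 at 560 nm) and the
#' CIE 1964 supplementary standard colorimetric observer colour-matching
#' functions (`"cmf_cie1964.csv"`), both as 10-nm CSV tabulations.
#'
#' @param file file name within the vendored table directory; with no
#'   argument, the available file names are returned.
#' @export
cie_path <- function(file = NULL) {
  dir <- system.file("extdata", "cie", package = "colorgamut", mustWork = TRUE)
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop(sprintf("no vendored CIE table '%s'", file), call. = FALSE)
  path
}

#' Load the vendored D65 illuminant or CIE 1964 observer
#'
#' Convenience wrappers around [load_spectral_table()] and [cie_path()].
#'
#' @inheritParams load_spectral_table
#' @export
cie_d65 <- function(grid = seq(380, 700, by = 1), interp = "spline") {
  load_spectral_table(cie_path("illuminant_d65.csv"), "illuminant",
                      grid = grid, interp = interp)
}

#' @rdname cie_d65
#' @export
cie_cmf1964 <- function(grid = seq(380, 700, by = 1), interp = "spline") {
  load_spectral_table(cie_path("cmf_cie1964.csv"), "cmf",
                      grid = grid, interp = interp)
}
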