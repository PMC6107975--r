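# Spectra are tibbles with columns `wavelength` (nm, strictly ascending) and
# `value` (non-negative), plus a `kind` attribute. Every operation returns a
# new spectrum; nothing is modified in place.

# hard bounds of any working grid, nm; display windows are narrower but
# computation always uses the full measured range within these bounds
.grid_lo <- 200
.grid_hi <- 1000

.spectrum_kinds <- c("intensity", "transmission", "reflection",
                     "absorption", "emission", "qe")

# kinds whose values are fractions of unity once on the canonical scale
.unit_kinds <- c("transmission", "reflection", "qe", "absorption")

#' Construct a spectrum
#'
#' A spectrum pairs wavelengths in nm with non-negative values and carries a
#' `kind` describing what the values mean. Vendor curves for transmission,
#' reflection, quantum efficiency, absorption and emission ship in either a
#' 0--1 or a 0--100 (percent) convention; if any value exceeds 2 the whole
#' column is treated as percent and divided by 100.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param value Numeric vector of non-negative values, same length.
#' @param kind One of `"intensity"`, `"transmission"`, `"reflection"`,
#'   `"absorption"`, `"emission"`, `"qe"`.
#' @return A tibble of class `lp_spectrum` with columns `wavelength` and
#'   `value` and a `kind` attribute.
#' @examples
#' spectrum(c(500, 510, 520), c(0.2, 1, 0.4), kind = "emission")
#' @export
spectrum <- function(wavelength, value, kind = "intensity") {
  kind <- match.arg(kind, .spectrum_kinds)
  if (length(wavelength) == 0L) {
    rlang::abort("no data points", class = "lp_empty_spectrum")
  }
  if (length(wavelength) != length(value)) {
    rlang::abort("wavelength and value must have the same length")
  }
  if (anyNA(wavelength) || anyNA(value)) {
    rlang::abort("spectrum contains missing values")
  }
  if (length(wavelength) > 1L && any(diff(wavelength) <= 0)) {
    rlang::abort("wavelengths must be strictly increasing")
  }
  if (any(value < 0)) {
    rlang::abort("spectrum values must be non-negative")
  }
  # percent-vs-fraction auto-detection for unit-bounded kinds
  if (kind %in% c(.unit_kinds, "emission") && max(value) > 2) {
    value <- value / 100
  }
  out <- tibble::tibble(wavelength = as.numeric(wavelength),
                        value = as.numeric(value))
  class(out) <- c("lp_spectrum", class(out))
  attr(out, "kind") <- kind
  out
}

#' @export
print.lp_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %g-%g nm>\n",
              spectrum_kind(x), nrow(x), min(x$wavelength), max(x$wavelength)))
  NextMethod()
}

#' Kind of a spectrum
#' @param s A spectrum created by [spectrum()].
#' @return A string.
#' @export
spectrum_kind <- function(s) attr(s, "kind") %||% "intensity"

#' Coerce a data frame to a spectrum
#' @param x A data frame whose first two columns are wavelength (nm) and value.
#' @param kind Spectrum kind, see [spectrum()].
#' @return An `lp_spectrum` tibble.
#' @export
as_spectrum <- function(x, kind = "intensity") {
  spectrum(x[[1]], x[[2]], kind = kind)
}

is_spectrum <- function(x) inherits(x, "lp_spectrum")

#' Resample a spectrum onto the integer-nanometre grid
#'
#' Linear interpolation between data points, evaluated at every integer nm in
#' `[lo, hi]`. Wavelengths outside the measured range of the data are assumed
#' to be zero. Resampling a spectrum already on the grid reproduces it exactly.
#'
#' @param s A spectrum.
#' @param lo,hi Integer grid bounds in nm; default the spectrum's own support.
#' @return A spectrum sampled at `lo:hi`.
#' @examples
#' s <- spectrum(c(500, 502), c(0, 1))
#' resample(s, 499, 503)$value
#' @export
resample <- function(s, lo = NULL, hi = NULL) {
  stopifnot(is_spectrum(s))
  if (nrow(s) == 0L) rlang::abort("no data points", class = "lp_empty_spectrum")
  lo <- if (is.null(lo)) floor(min(s$wavelength)) else as.integer(lo)
  hi <- if (is.null(hi)) ceiling(max(s$wavelength)) else as.integer(hi)
  if (lo >= hi) rlang::abort("grid bounds must satisfy lo < hi")
  grid <- seq(lo, hi)
  if (nrow(s) == 1L) {
    v <- ifelse(grid == s$wavelength, s$value, 0)
  } else {
    v <- stats::approx(s$wavelength, s$value, xout = grid,
                       method = "linear", yleft = 0, yright = 0,
                       ties = "ordered")$y
  }
  spectrum(grid, v, kind = spectrum_kind(s))
}

# union support of a list of spectra, clamped to the hard grid bounds
.union_grid <- function(spectra) {
  lo <- max(.grid_lo, floor(min(vapply(spectra, function(s) min(s$wavelength), 0))))
  hi <- min(.grid_hi, ceiling(max(vapply(spectra, function(s) max(s$wavelength), 0))))
  if (lo >= hi) {
    # degenerate (single shared wavelength at a clamp edge); widen minimally
    hi <- lo + 1L
  }
  c(lo, hi)
}

#' Pointwise product of spectra
#'
#' Operands are resampled to the integer grid spanning the union of their
#' supports (clamped to 200--1000 nm) and multiplied pointwise; outside its
#' measured range every operand contributes zero. Commutative and associative.
#'
#' @param ... Two or more spectra, or a single list of spectra.
#' @param kind Kind attached to the product (default `"intensity"`).
#' @return A spectrum on the union grid.
#' @export
spc_multiply <- function(..., kind = "intensity") {
  ops <- list(...)
  if (length(ops) == 1L && !is_spectrum(ops[[1]])) ops <- ops[[1]]
  if (length(ops) < 2L) rlang::abort("need at least two operands")
  stopifnot(all(vapply(ops, is_spectrum, TRUE)))
  g <- .union_grid(ops)
  vals <- lapply(ops, function(s) resample(s, g[1], g[2])$value)
  spectrum(seq(g[1], g[2]), Reduce(`*`, vals), kind = kind)
}

#' Area under a spectrum
#'
#' Trapezoidal integral over the 1 nm grid, in value-times-nm. The spectrum is
#' resampled to the integer grid over its own support first, so the result is
#' the exact integral of the piecewise-linear interpolant sampled at 1 nm.
#'
#' @param s A spectrum.
#' @return Non-negative scalar.
#' @examples
#' spc_area(spectrum(c(400, 500), c(1, 1)))  # 100
#' @export
spc_area <- function(s) {
  stopifnot(is_spectrum(s))
  # a lone 1 nm sample is a unit-width triangular pulse under zero-extension
  if (nrow(s) == 1L) return(s$value)
  r <- resample(s)
  pracma::trapz(r$wavelength, r$value)
}

#' Complement of a unit-bounded spectrum (transmission <-> reflection)
#'
#' Lossless optics are assumed, so reflection = 1 - transmission. The
#' complement is only defined over the measured wavelength range: the result
#' keeps the same support, and zero-extension applies to whatever spectrum the
#' complement finally multiplies into, so a reflection-mode filter contributes
#' nothing outside its measured range rather than perfect reflectivity.
#'
#' @param s A transmission or reflection spectrum with values in `[0, 1]`.
#' @return A spectrum of the opposite kind over the same wavelengths.
#' @export
spc_complement <- function(s) {
  stopifnot(is_spectrum(s))
  kind <- spectrum_kind(s)
  if (!kind %in% c("transmission", "reflection")) {
    rlang::abort("complement is defined for transmission or reflection spectra")
  }
  if (any(s$value > 1)) {
    rlang::abort("not a unit-bounded spectrum")
  }
  spectrum(s$wavelength, 1 - s$value,
           kind = if (kind == "transmission") "reflection" else "transmission")
}

#' Normalise a spectrum to unit peak
#'
#' Divides all values by the maximum. Dye absorption spectra are stored this
#' way so that the fraction of light absorbed equals 1 at the absorption
#' maximum; emission spectra need no normalisation because collection
#' efficiency is a ratio of areas in which any scale cancels.
#'
#' @param s A spectrum with a positive maximum.
#' @return A spectrum with maximum value 1.
#' @export
peak_normalize <- function(s) {
  stopifnot(is_spectrum(s))
  m <- max(s$value)
  if (m <= 0) rlang::abort("cannot peak-normalize an all-zero spectrum")
  spectrum(s$wavelength, s$value / m, kind = spectrum_kind(s))
}
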