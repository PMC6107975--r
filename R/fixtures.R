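# Deterministic synthetic components: Gaussian dyes, box band-pass filters,
# sigmoidal edge dichroics, 1 nm laser lines, flat lamps and detectors. These
# generate the same idealised shapes the published component collections
# contain, sampled on the 1 nm grid, so the whole test suite runs with no
# external data. Generators are pure functions of their arguments.

#' Synthetic Gaussian dye
#'
#' Unit-peak Gaussian absorption and emission bands sampled at 1 nm over
#' mean +/- 5 sigma. The emission peak must lie red of the absorption peak
#' (a positive Stokes shift).
#'
#' @param mu_abs,mu_em Absorption and emission peak wavelengths, nm.
#' @param sigma Common Gaussian width, nm.
#' @param ext_coeff Extinction coefficient, M^-1 cm^-1 (`NA` allowed).
#' @param q_yield Quantum yield (`NA` allowed).
#' @param id Component id.
#' @return An `lp_dye`.
#' @examples
#' d <- gaussian_dye(590, 610, 15, 90000, 0.8)
#' d$absorption$value[d$absorption$wavelength == 590]  # 1
#' @export
gaussian_dye <- function(mu_abs, mu_em, sigma, ext_coeff = NA_real_,
                         q_yield = NA_real_, id = NULL) {
  if (mu_em <= mu_abs) {
    rlang::abort("emission peak must be at a longer wavelength than absorption (Stokes shift)")
  }
  id <- id %||% sprintf("dye-%g-%g", mu_abs, mu_em)
  gauss <- function(mu) {
    wl <- seq(round(mu - 5 * sigma), round(mu + 5 * sigma))
    list(wl = wl, v = exp(-(wl - mu)^2 / (2 * sigma^2)))
  }
  a <- gauss(mu_abs)
  e <- gauss(mu_em)
  dye(id,
      absorption = spectrum(a$wl, a$v, kind = "absorption"),
      emission = spectrum(e$wl, e$v, kind = "emission"),
      ext_coeff = ext_coeff, q_yield = q_yield)
}

#' Synthetic box band-pass filter
#'
#' Transmission `t_pass` strictly inside `(lo, hi)`, `t_stop` outside, and
#' the midpoint `(t_pass + t_stop) / 2` at `lo` and `hi` themselves: filter
#' cut-on and cut-off wavelengths are conventionally the 50% transmission
#' points, and with 1 nm sampling this places the interpolated half-height
#' edge exactly at the stated wavelengths.
#'
#' @param lo,hi Cut-on and cut-off wavelengths, nm.
#' @param t_pass Pass-band transmission (default 1).
#' @param t_stop Stop-band transmission (default 0).
#' @param pad Stop-band extent modelled beyond each edge, nm.
#' @param id Component id.
#' @return An `lp_filter`.
#' @export
box_filter <- function(lo, hi, t_pass = 1, t_stop = 0, pad = 50, id = NULL) {
  stopifnot(lo < hi, t_stop <= t_pass, t_pass <= 1)
  id <- id %||% sprintf("box-%g-%g", lo, hi)
  wl <- seq(lo - pad, hi + pad)
  v <- ifelse(wl > lo & wl < hi, t_pass,
              ifelse(wl == lo | wl == hi, (t_pass + t_stop) / 2, t_stop))
  light_filter(id, spectrum(wl, v, kind = "transmission"))
}

#' Synthetic edge (long-pass) dichroic
#'
#' Sigmoidal transmission edge rising with wavelength:
#' `t_stop + (t_pass - t_stop) / (1 + exp(-(lambda - lambda_cut) / width))`,
#' so the transmission at `lambda_cut` is exactly midway between the stop and
#' pass levels. Reflection-mode behaviour follows from the lossless
#' complement.
#'
#' @param lambda_cut Edge wavelength, nm (50% point).
#' @param width Edge steepness scale, nm.
#' @param t_pass,t_stop Asymptotic transmission above/below the edge.
#' @param span Modelled range beyond the edge on each side, nm.
#' @param id Component id.
#' @return An `lp_filter`.
#' @export
edge_dichroic <- function(lambda_cut, width = 5, t_pass = 0.98, t_stop = 0.02,
                          span = 150, id = NULL) {
  stopifnot(width > 0, t_stop < t_pass, t_pass <= 1)
  id <- id %||% sprintf("dichroic-%g", lambda_cut)
  wl <- seq(lambda_cut - span, lambda_cut + span)
  v <- t_stop + (t_pass - t_stop) * stats::plogis((wl - lambda_cut) / width)
  light_filter(id, spectrum(wl, v, kind = "transmission"))
}

#' Synthetic laser line
#'
#' Lasers are modelled as unit pulses 1 nm wide: a single grid sample of
#' value 1 at `lambda0`, zero everywhere else by zero-extension. The
#' trapezoidal area of the resulting triangular pulse is 1 value-nm.
#'
#' @param lambda0 Laser wavelength, nm (integer grid point).
#' @param id Component id.
#' @return An `lp_excitation`.
#' @export
laser_line <- function(lambda0, id = NULL) {
  id <- id %||% sprintf("laser-%g", lambda0)
  excitation(id, spectrum(lambda0, 1, kind = "intensity"))
}

#' Synthetic flat lamp
#' @param lo,hi Emission range, nm.
#' @param level Constant spectral intensity (arbitrary units).
#' @param id Component id.
#' @return An `lp_excitation` with constant intensity over `[lo, hi]`.
#' @export
flat_lamp <- function(lo, hi, level = 1, id = NULL) {
  stopifnot(lo < hi, level > 0)
  id <- id %||% sprintf("lamp-%g-%g", lo, hi)
  excitation(id, spectrum(seq(lo, hi), rep(level, hi - lo + 1),
                          kind = "intensity"))
}

#' Synthetic flat detector
#' @param level Constant quantum efficiency in `(0, 1]`.
#' @param lo,hi Sensitive range, nm.
#' @param id Component id.
#' @return An `lp_detector`.
#' @export
flat_detector <- function(level = 1, lo = 200, hi = 1000, id = NULL) {
  stopifnot(level > 0, level <= 1)
  id <- id %||% sprintf("detector-%g", level)
  detector(id, spectrum(c(lo, hi), c(level, level), kind = "qe"))
}

# ---- serialisation to the file dialect ---------------------------------

#' Convert a component to a spectrum file record
#'
#' Builds the file representation of a synthetic (or any in-memory)
#' component so it can be written with [save_spectrum_file()] and read back
#' through a collection; round-tripping is lossless.
#'
#' @param component An `lp_dye`, `lp_excitation`, `lp_detector` or
#'   `lp_filter`.
#' @return An `lp_spectrum_file` record.
#' @export
component_record <- function(component) {
  rec <- function(header, data, comments = character()) {
    structure(list(header = header, comments = comments,
                   data = tibble::as_tibble(data),
                   source = component$id),
              class = "lp_spectrum_file")
  }
  if (inherits(component, "lp_dye")) {
    # absorption and emission may live on different supports; merge on the
    # union grid (zero outside each band)
    g <- .union_grid(list(component$absorption, component$emission))
    a <- resample(component$absorption, g[1], g[2])
    e <- resample(component$emission, g[1], g[2])
    hdr <- c(name = component$id, type = "dye")
    if (!is.na(component$ext_coeff)) {
      hdr <- c(hdr, extinction_coefficient = trimws(
        formatC(component$ext_coeff, digits = 15, format = "g")))
    }
    if (!is.na(component$q_yield)) {
      hdr <- c(hdr, quantum_yield = trimws(
        formatC(component$q_yield, digits = 15, format = "g")))
    }
    rec(hdr, list(wavelength = a$wavelength, absorption = a$value,
                  emission = e$value))
  } else if (inherits(component, "lp_excitation")) {
    rec(c(name = component$id, type = "excitation"),
        list(wavelength = component$intensity$wavelength,
             intensity = component$intensity$value))
  } else if (inherits(component, "lp_detector")) {
    rec(c(name = component$id, type = "detector"),
        list(wavelength = component$qe$wavelength, qe = component$qe$value))
  } else if (inherits(component, "lp_filter")) {
    rec(c(name = component$id, type = "filter"),
        list(wavelength = component$transmission$wavelength,
             transmission = component$transmission$value))
  } else {
    rlang::abort("not a light-path component")
  }
}

#' Write a set of components as an on-disk collection
#'
#' Writes one spectrum file per component plus a JSON index, producing a
#' directory [load_collection()] can read.
#'
#' @param components List of components of one kind.
#' @param directory Destination directory (created if needed).
#' @param kind Component kind; inferred from the first element if missing.
#' @return The index file path, invisibly.
#' @export
write_collection <- function(components, directory, kind = NULL) {
  if (is.null(kind)) {
    kind <- switch(class(components[[1]])[1],
                   lp_dye = "dye", lp_excitation = "excitation",
                   lp_detector = "detector", lp_filter = "filter",
                   rlang::abort("cannot infer component kind"))
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(components, function(cmp) {
    f <- paste0(cmp$id, ".csv")
    save_spectrum_file(component_record(cmp), file.path(directory, f))
    f
  }, character(1))
  index <- file.path(directory, paste0(kind, "s.json"))
  jsonlite::write_json(unname(files), index)
  invisible(index)
}
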