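# Excitation efficiency, emission (collection) efficiency, relative
# brightness, dye ranking and bleedthrough. All integrals for one efficiency
# are evaluated on a single shared integer-nm grid so that numerator and
# denominator see identical interpolation and boundary treatment.

#' Reference constants for the brightness score
#'
#' Brightness is reported relative to an ideal setup exciting and collecting
#' 100% of an Alexa-488-like reference dye (extinction coefficient
#' 73000 M^-1 cm^-1, quantum yield 0.92), and multiplied by 10.
#'
#' @param ref_ext_coeff Reference extinction coefficient, M^-1 cm^-1.
#' @param ref_q_yield Reference quantum yield.
#' @param scale Overall multiplier applied to the normalised score.
#' @return A list of class `lp_reference`.
#' @export
reference_constants <- function(ref_ext_coeff = 73000, ref_q_yield = 0.92,
                                scale = 10) {
  structure(list(ref_ext_coeff = ref_ext_coeff, ref_q_yield = ref_q_yield,
                 scale = scale),
            class = "lp_reference")
}

# detector qe, or unit efficiency across the working range when absent
.setup_qe <- function(setup) {
  if (is.null(setup$detector)) {
    spectrum(c(.grid_lo, .grid_hi), c(1, 1), kind = "qe")
  } else {
    setup$detector$qe
  }
}

# trapezoid over a spectrum already on the shared grid (no re-extension)
.grid_area <- function(s) pracma::trapz(s$wavelength, s$value)

#' Transmitted fluorescence spectrum
#'
#' The product of the dye emission spectrum, the total transmission of every
#' filter in the emission path, and the detector's wavelength-dependent
#' quantum efficiency.
#'
#' @param setup An [optical_setup()].
#' @return An intensity spectrum on the working grid.
#' @export
transmitted_spectrum <- function(setup) {
  stopifnot(inherits(setup, "lp_setup"))
  spc_multiply(setup$dye$emission, stack_total(setup$em_path),
               .setup_qe(setup), kind = "intensity")
}

#' Emission (collection) efficiency
#'
#' Area of the transmitted spectrum divided by the area of the dye emission
#' spectrum, both on the same working grid; a fraction in `[0, 1]`.
#'
#' @param setup An [optical_setup()].
#' @return Scalar fraction.
#' @export
emission_efficiency <- function(setup) {
  tr <- transmitted_spectrum(setup)
  g <- range(tr$wavelength)
  em_area <- .grid_area(resample(setup$dye$emission, g[1], g[2]))
  if (em_area <= 0) rlang::abort("dye emission spectrum has zero area")
  min(1, .grid_area(tr) / em_area)
}

#' Source spectrum after the excitation path
#'
#' The excitation source modulated by every filter and dichroic in the
#' excitation path; this is also the source trace shown in plots.
#'
#' @param setup An [optical_setup()].
#' @return An intensity spectrum.
#' @export
attenuated_source <- function(setup) {
  spc_multiply(setup$excitation$intensity, stack_total(setup$ex_path),
               kind = "intensity")
}

#' Excitation efficiency
#'
#' Fraction of the source light absorbed by the dye: the area of the source
#' spectrum modulated by the excitation-path filters and the (peak-normalised)
#' dye absorption spectrum, divided by the area of the unmodulated source, on
#' a common working grid.
#'
#' @param setup An [optical_setup()].
#' @return Scalar fraction in `[0, 1]`.
#' @export
excitation_efficiency <- function(setup) {
  stopifnot(inherits(setup, "lp_setup"))
  absorbed <- spc_multiply(setup$excitation$intensity,
                           stack_total(setup$ex_path),
                           setup$dye$absorption, kind = "intensity")
  g <- range(absorbed$wavelength)
  src_area <- .grid_area(resample(setup$excitation$intensity, g[1], g[2]))
  if (src_area <= 0) rlang::abort("excitation source spectrum has zero area")
  min(1, .grid_area(absorbed) / src_area)
}

#' Relative brightness score
#'
#' The product of excitation efficiency, emission efficiency, dye extinction
#' coefficient and dye quantum yield, normalised to 100% excitation and
#' emission of the reference dye and multiplied by the reference scale
#' (10 by default). A hypothetical dye matching the reference constants in a
#' lossless all-pass setup therefore scores exactly 10.
#'
#' @param setup An [optical_setup()] whose dye carries `ext_coeff` and
#'   `q_yield`.
#' @param reference See [reference_constants()].
#' @return Non-negative scalar.
#' @export
brightness <- function(setup, reference = reference_constants()) {
  d <- setup$dye
  if (is.na(d$ext_coeff) || is.na(d$q_yield)) {
    rlang::abort(sprintf(
      "brightness unavailable: dye '%s' lacks extinction coefficient or quantum yield",
      d$id), class = "lp_no_constants")
  }
  reference$scale * excitation_efficiency(setup) * emission_efficiency(setup) *
    (d$ext_coeff * d$q_yield) /
    (reference$ref_ext_coeff * reference$ref_q_yield)
}

#' Full efficiency report for a setup
#'
#' Computes both efficiencies, the brightness score (when the dye carries the
#' needed constants), the transmitted fluorescence spectrum and the
#' attenuated source trace. Efficiencies are kept at full precision; the
#' print method renders them as percentages with one decimal and brightness
#' with two, the package's reporting convention.
#'
#' @param setup An [optical_setup()].
#' @param reference See [reference_constants()].
#' @return An object of class `lp_report`.
#' @examples
#' d <- gaussian_dye(mu_abs = 560, mu_em = 590, sigma = 15,
#'                   ext_coeff = 73000, q_yield = 0.92)
#' s <- optical_setup(laser_line(560), d)
#' light_report(s)
#' @export
light_report <- function(setup, reference = reference_constants()) {
  stopifnot(inherits(setup, "lp_setup"))
  notes <- character()
  if (is.null(setup$detector)) {
    notes <- c(notes, "no detector selected; unit quantum efficiency assumed")
  }
  ex <- excitation_efficiency(setup)
  em <- emission_efficiency(setup)
  d <- setup$dye
  if (is.na(d$ext_coeff) || is.na(d$q_yield)) {
    br <- NA_real_
    notes <- c(notes, sprintf(
      "dye '%s' lacks extinction coefficient or quantum yield; brightness unavailable",
      d$id))
  } else {
    br <- reference$scale * ex * em * (d$ext_coeff * d$q_yield) /
      (reference$ref_ext_coeff * reference$ref_q_yield)
  }
  structure(list(setup = setup, ex_eff = ex, em_eff = em, brightness = br,
                 transmitted = transmitted_spectrum(setup),
                 attenuated_source = attenuated_source(setup),
                 notes = notes),
            class = "lp_report")
}

#' @export
print.lp_report <- function(x, ...) {
  br <- if (is.na(x$brightness)) "n/a" else sprintf("%.2f", x$brightness)
  cat(sprintf("ex %.1f%%  em %.1f%%  brightness %s\n",
              100 * x$ex_eff, 100 * x$em_eff, br))
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of an efficiency report
#' @param x An `lp_report`.
#' @param ... Unused.
#' @return A one-row tibble with `dye`, `ex_eff`, `em_eff`, `brightness`.
#' @method glance lp_report
#' @export
glance.lp_report <- function(x, ...) {
  tibble::tibble(dye = x$setup$dye$id, ex_eff = x$ex_eff, em_eff = x$em_eff,
                 brightness = x$brightness)
}

#' Long table of the report's spectral traces
#' @param x An `lp_report`.
#' @param ... Unused.
#' @return A tibble with columns `trace`, `wavelength`, `value`.
#' @method tidy lp_report
#' @export
tidy.lp_report <- function(x, ...) {
  dplyr::bind_rows(.id = "trace", purrr::map(.report_traces(x), function(s) {
    tibble::tibble(wavelength = s$wavelength, value = s$value)
  }))
}

#' Rank a dye collection against a fixed setup
#'
#' Evaluates every dye in the collection in the given setup (all other
#' components unchanged) and returns one row per dye, sorted by brightness in
#' descending order with ties broken by dye id. Dyes lacking an extinction
#' coefficient or quantum yield keep their efficiency columns, get an `NA`
#' brightness, sort last, and are flagged.
#'
#' @param setup An [optical_setup()].
#' @param dye_collection An `lp_collection` of dyes, or a list of `lp_dye`
#'   objects.
#' @param sort_by `"brightness"` (default), `"ex"` or `"em"`.
#' @param reference See [reference_constants()].
#' @return A tibble with columns `dye`, `ex_eff`, `em_eff`, `brightness`,
#'   `missing_constants`.
#' @export
optimise_dyes <- function(setup, dye_collection,
                          sort_by = c("brightness", "ex", "em"),
                          reference = reference_constants()) {
  sort_by <- match.arg(sort_by)
  if (!inherits(dye_collection, "lp_collection")) {
    dye_collection <- collection_from_list(dye_collection, kind = "dye")
  }
  ids <- collection_ids(dye_collection)
  if (length(ids) == 0L) rlang::abort("empty dye collection")
  rows <- purrr::map(ids, function(id) {
    r <- light_report(swap_dye(setup, collection_get(dye_collection, id)),
                      reference = reference)
    tibble::tibble(dye = id, ex_eff = r$ex_eff, em_eff = r$em_eff,
                   brightness = r$brightness,
                   missing_constants = is.na(r$brightness))
  })
  tbl <- dplyr::bind_rows(rows)
  key <- switch(sort_by, brightness = dplyr::coalesce(tbl$brightness, -Inf),
                ex = tbl$ex_eff, em = tbl$em_eff)
  dplyr::arrange(tbl, dplyr::desc(key), .data$dye)
}

#' Write a dye ranking as CSV
#' @param ranking A tibble from [optimise_dyes()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.csv(ranking[c("dye", "ex_eff", "em_eff", "brightness")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Cross-channel bleedthrough estimate
#'
#' For a detection channel configured for `on_dye`, the expected bleedthrough
#' from an equal amount of `off_dye` is the ratio of the two dyes' brightness
#' scores evaluated in the same channel setup.
#'
#' @param channel_setup The channel's [optical_setup()]; its current dye is
#'   ignored.
#' @param on_dye The dye the channel is designed to detect (`lp_dye`).
#' @param off_dye The potentially bleeding dye (`lp_dye`).
#' @param reference See [reference_constants()].
#' @return Scalar ratio (1 means equal signal; 0 means no bleedthrough).
#' @export
bleedthrough <- function(channel_setup, on_dye, off_dye,
                         reference = reference_constants()) {
  b_on <- brightness(swap_dye(channel_setup, on_dye), reference = reference)
  if (b_on <= 0) {
    rlang::abort("channel does not detect its own dye (zero brightness)")
  }
  brightness(swap_dye(channel_setup, off_dye), reference = reference) / b_on
}
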