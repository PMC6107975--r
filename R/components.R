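# Optical components and their composition into a setup. All components are
# immutable value objects; "swapping" a component builds a new setup.

#' Dye
#'
#' A fluorescent dye: absorption and emission spectra plus the photophysical
#' constants used for brightness. The absorption spectrum is peak-normalised
#' to 1 at construction so the absorbed fraction equals 1 at the absorption
#' maximum; the emission spectrum is kept as supplied because collection
#' efficiency is a ratio of areas in which its scale cancels.
#'
#' @param id Component id.
#' @param absorption,emission Spectra (see [spectrum()]).
#' @param ext_coeff Molar extinction coefficient at peak absorption,
#'   M^-1 cm^-1; `NA` if unknown (brightness then unavailable).
#' @param q_yield Quantum yield in `(0, 1]`; `NA` if unknown.
#' @return An `lp_dye` object.
#' @export
dye <- function(id, absorption, emission, ext_coeff = NA_real_,
                q_yield = NA_real_) {
  stopifnot(is_spectrum(absorption), is_spectrum(emission))
  if (!is.na(ext_coeff) && ext_coeff <= 0) {
    rlang::abort("extinction coefficient must be positive")
  }
  if (!is.na(q_yield) && (q_yield <= 0 || q_yield > 1)) {
    rlang::abort("quantum yield must be in (0, 1]")
  }
  structure(list(id = id, absorption = peak_normalize(absorption),
                 emission = emission,
                 ext_coeff = as.numeric(ext_coeff),
                 q_yield = as.numeric(q_yield)),
            class = "lp_dye")
}

#' Excitation source
#' @param id Component id.
#' @param intensity Intensity spectrum (arbitrary units).
#' @return An `lp_excitation` object.
#' @export
excitation <- function(id, intensity) {
  stopifnot(is_spectrum(intensity))
  structure(list(id = id, intensity = intensity), class = "lp_excitation")
}

#' Detector
#' @param id Component id.
#' @param qe Quantum-efficiency spectrum, values in `[0, 1]`.
#' @return An `lp_detector` object.
#' @export
detector <- function(id, qe) {
  stopifnot(is_spectrum(qe))
  structure(list(id = id, qe = qe), class = "lp_detector")
}

#' Filter or dichroic
#' @param id Component id.
#' @param transmission Transmission spectrum, values in `[0, 1]`. Reflectivity
#'   is derived as `1 - transmission` under the lossless assumption.
#' @return An `lp_filter` object.
#' @export
light_filter <- function(id, transmission) {
  stopifnot(is_spectrum(transmission))
  if (any(transmission$value > 1)) {
    rlang::abort("not a unit-bounded spectrum")
  }
  structure(list(id = id, transmission = transmission), class = "lp_filter")
}

#' Ordered filter stack
#'
#' Each filter sits in the stack in transmission mode (`"T"`, light passes
#' through) or reflection mode (`"R"`, light bounces off; the effective
#' spectrum is the complement of its transmission). The same filter id may
#' appear more than once (double-pass), in which case its attenuation is
#' applied each time.
#'
#' @param filters List of `lp_filter` objects (possibly empty).
#' @param modes Character vector of `"T"`/`"R"`, one per filter.
#' @return An `lp_stack` object.
#' @export
filter_stack <- function(filters = list(), modes = character()) {
  stopifnot(length(filters) == length(modes))
  modes <- toupper(modes)
  if (!all(modes %in% c("T", "R"))) {
    rlang::abort("filter modes must be 'T' or 'R'")
  }
  structure(list(filters = filters, modes = modes), class = "lp_stack")
}

#' @export
length.lp_stack <- function(x) length(x$filters)

#' Append a filter to a stack
#' @param stack An `lp_stack`.
#' @param filter An `lp_filter`.
#' @param mode `"T"` or `"R"`.
#' @return A new `lp_stack` with the filter appended.
#' @export
stack_append <- function(stack, filter, mode = "T") {
  filter_stack(c(stack$filters, list(filter)), c(stack$modes, mode))
}

# effective per-placement spectrum: transmission in T mode, its lossless
# complement in R mode (defined only over the measured range; the product is
# zero-extended beyond it, i.e. an R-mode filter is opaque where unmeasured)
.effective_spectrum <- function(filter, mode) {
  if (mode == "T") filter$transmission else spc_complement(filter$transmission)
}

#' Total transmission of a filter stack
#'
#' Pointwise product of every placement's effective spectrum on the common
#' integer grid. An empty stack is the identity: all-ones over the full
#' working range. The product commutes, so placement order never changes the
#' result.
#'
#' @param stack An `lp_stack`.
#' @return A transmission spectrum.
#' @export
stack_total <- function(stack) {
  stopifnot(inherits(stack, "lp_stack"))
  if (length(stack) == 0L) {
    return(spectrum(c(.grid_lo, .grid_hi), c(1, 1), kind = "transmission"))
  }
  eff <- purrr::map2(stack$filters, stack$modes, .effective_spectrum)
  if (length(eff) == 1L) {
    return(resample(eff[[1]]))
  }
  spc_multiply(eff, kind = "transmission")
}

#' Optical setup
#'
#' The unit of evaluation: an excitation source, the excitation-path filter
#' stack, a dye, the emission-path filter stack, and a detector. The detector
#' may be omitted, in which case unit quantum efficiency is assumed across
#' the working range and the report notes it.
#'
#' @param excitation An `lp_excitation`.
#' @param dye An `lp_dye`.
#' @param detector An `lp_detector`, or `NULL` for an ideal detector.
#' @param ex_path,em_path `lp_stack` objects (default empty).
#' @param name Optional setup name.
#' @return An `lp_setup` object.
#' @export
optical_setup <- function(excitation, dye, detector = NULL,
                          ex_path = filter_stack(), em_path = filter_stack(),
                          name = NULL) {
  stopifnot(inherits(excitation, "lp_excitation"), inherits(dye, "lp_dye"),
            inherits(ex_path, "lp_stack"), inherits(em_path, "lp_stack"))
  if (!is.null(detector)) stopifnot(inherits(detector, "lp_detector"))
  structure(list(name = name, excitation = excitation, ex_path = ex_path,
                 dye = dye, em_path = em_path, detector = detector),
            class = "lp_setup")
}

#' @export
print.lp_setup <- function(x, ...) {
  cat(sprintf("<optical setup%s: excitation %s, dye %s, detector %s, %d ex / %d em filters>\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$excitation$id, x$dye$id,
              if (is.null(x$detector)) "(ideal)" else x$detector$id,
              length(x$ex_path), length(x$em_path)))
  invisible(x)
}

#' Resolve a setup description against component collections
#'
#' A setup description names its components by id; resolution looks each id
#' up in the matching collection and materialises a full [optical_setup()].
#' Collections are not modified.
#'
#' @param desc An `lp_setup_description` from [parse_setups()].
#' @param collections Named list with elements `dyes`, `excitations`,
#'   `detectors`, `filters`, each an `lp_collection`.
#' @param dye_override,excitation_override,detector_override Optional ids
#'   replacing the description's choices before lookup.
#' @return An `lp_setup`.
#' @export
resolve_setup <- function(desc, collections, dye_override = NULL,
                          excitation_override = NULL, detector_override = NULL) {
  stopifnot(inherits(desc, "lp_setup_description"))
  get_from <- function(kind_plural, id) {
    col <- collections[[kind_plural]]
    if (is.null(col)) rlang::abort(sprintf("no %s collection supplied", kind_plural))
    collection_get(col, id)
  }
  path_of <- function(p) {
    filter_stack(purrr::map(p, function(e) get_from("filters", e$filter)),
                 purrr::map_chr(p, "mode"))
  }
  det_id <- detector_override %||% desc$detector
  optical_setup(
    excitation = get_from("excitations", excitation_override %||% desc$excitation),
    dye = get_from("dyes", dye_override %||% desc$dye),
    detector = if (is.null(det_id)) NULL else get_from("detectors", det_id),
    ex_path = path_of(desc$ex_path),
    em_path = path_of(desc$em_path),
    name = desc$name)
}

#' Swap one component of a setup
#'
#' Returns a new setup sharing every other component; the original setup is
#' untouched. Used by [optimise_dyes()] to sweep a dye collection against a
#' fixed filter configuration.
#'
#' @param setup An `lp_setup`.
#' @param dye,excitation,detector Replacement component.
#' @return A new `lp_setup`.
#' @export
swap_dye <- function(setup, dye) {
  stopifnot(inherits(setup, "lp_setup"), inherits(dye, "lp_dye"))
  setup$dye <- dye
  setup
}

#' @rdname swap_dye
#' @export
swap_excitation <- function(setup, excitation) {
  stopifnot(inherits(setup, "lp_setup"), inherits(excitation, "lp_excitation"))
  setup$excitation <- excitation
  setup
}

#' @rdname swap_dye
#' @export
swap_detector <- function(setup, detector) {
  stopifnot(inherits(setup, "lp_setup"))
  if (!is.null(detector)) stopifnot(inherits(detector, "lp_detector"))
  setup$detector <- detector
  setup
}
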