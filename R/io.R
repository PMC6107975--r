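# Plain-text spectrum files: a multi-line header of "key: value" pairs and
# '#' comments, followed by a CSV section whose first column is wavelength in
# nm (ascending) and whose remaining columns are named value series.

# header keys with recognised meanings (matched case-insensitively); anything
# else is preserved verbatim
.known_keys <- c("name", "type", "extinction_coefficient", "quantum_yield",
                 "mode_default")

#' Parse a spectrum file
#'
#' Reads the plain-text dialect used for component spectra: lines starting
#' with `#` are comments, lines of the form `key: value` before the CSV
#' section form an ordered header, and the remainder is CSV with a header row
#' naming the columns. Numbers use the dot decimal separator regardless of
#' locale. Both `\n` and `\r\n` line endings are accepted.
#'
#' @param text A single string, or a character vector of lines.
#' @param source Optional identifier (e.g. a file path) used in error messages.
#' @return A list of class `lp_spectrum_file` with elements `header` (named
#'   character vector, order preserved), `comments` (character vector),
#'   `data` (tibble; first column `wavelength`), and `source`.
#' @export
parse_spectrum_file <- function(text, source = "<text>") {
  if (length(text) == 1L) {
    lines <- strsplit(gsub("\r\n", "\n", text), "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  if (length(lines) == 0L || !any(nzchar(trimws(lines)))) {
    rlang::abort(sprintf("%s: empty file", source))
  }
  comments <- character()
  keys <- character()
  vals <- character()
  csv_start <- NA_integer_
  header_re <- "^\\s*([^,:#][^,:]*):\\s*(.*)$"
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(trimws(ln), "#")) {
      comments <- c(comments, sub("^\\s*#\\s?", "", ln))
      next
    }
    if (grepl(header_re, ln)) {
      keys <- c(keys, trimws(sub(header_re, "\\1", ln)))
      vals <- c(vals, trimws(sub(header_re, "\\2", ln)))
      next
    }
    csv_start <- i
    break
  }
  if (is.na(csv_start)) {
    rlang::abort(sprintf("%s: no spectral data", source))
  }
  dup <- duplicated(tolower(keys), fromLast = TRUE)
  if (any(dup)) {
    rlang::warn(sprintf("%s: duplicate header key(s) %s; last occurrence wins",
                        source, paste(unique(keys[dup]), collapse = ", ")))
    keep <- !dup
    keys <- keys[keep]
    vals <- vals[keep]
  }
  header <- stats::setNames(vals, keys)

  csv_lines <- lines[csv_start:length(lines)]
  csv_lines <- csv_lines[nzchar(trimws(csv_lines)) &
                           !startsWith(trimws(csv_lines), "#")]
  if (length(csv_lines) < 2L) {
    rlang::abort(sprintf("%s: no spectral data", source))
  }
  col_names <- trimws(strsplit(csv_lines[[1]], ",", fixed = TRUE)[[1]])
  body <- utils::read.csv(text = csv_lines[-1], header = FALSE,
                          col.names = col_names, check.names = FALSE,
                          colClasses = "character", strip.white = TRUE)
  # locale-independent numeric parse with line/column reporting
  num <- as.data.frame(lapply(body, function(col) {
    suppressWarnings(as.numeric(col))
  }), check.names = FALSE)
  bad <- which(is.na(as.matrix(num)) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    rlang::abort(sprintf(
      "%s: non-numeric value '%s' at line %d, column '%s'",
      source, body[bad[1, 1], bad[1, 2]],
      csv_start + bad[1, 1], col_names[bad[1, 2]]))
  }
  wl <- num[[1]]
  if (anyNA(wl)) {
    rlang::abort(sprintf("%s: missing wavelength value", source))
  }
  if (length(wl) > 1L && any(diff(wl) <= 0)) {
    i <- which(diff(wl) <= 0)[1]
    rlang::abort(sprintf(
      "%s: wavelengths not strictly increasing at line %d (%g after %g)",
      source, csv_start + 1L + i, wl[i + 1], wl[i]))
  }
  data <- tibble::as_tibble(num)
  names(data)[1] <- "wavelength"
  structure(list(header = header, comments = comments, data = data,
                 source = source),
            class = "lp_spectrum_file")
}

#' Read a spectrum file from disk
#' @param path Path to a spectrum file.
#' @return An `lp_spectrum_file` record; see [parse_spectrum_file()].
#' @export
read_spectrum_file <- function(path) {
  parse_spectrum_file(readLines(path, warn = FALSE), source = path)
}

#' Serialise a spectrum file record
#'
#' Inverse of [parse_spectrum_file()] up to whitespace: comments first, then
#' header keys in their original order, then the CSV section. Numeric
#' formatting is deterministic (up to 15 significant digits), so writing,
#' re-parsing and writing again is byte-identical.
#'
#' @param record An `lp_spectrum_file` record.
#' @return A single string.
#' @export
write_spectrum_file <- function(record) {
  stopifnot(inherits(record, "lp_spectrum_file"))
  data <- record$data
  if (nrow(data) == 0L || ncol(data) < 2L) {
    rlang::abort("record has no spectral data to write")
  }
  fmt <- function(x) {
    trimws(vapply(x, function(v) formatC(v, digits = 15, format = "g"),
                  character(1)))
  }
  lines <- c(
    if (length(record$comments)) paste0("# ", record$comments),
    if (length(record$header)) paste0(names(record$header), ": ", record$header),
    paste(names(data), collapse = ","),
    do.call(paste, c(lapply(data, fmt), sep = ","))
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname write_spectrum_file
#' @param path Destination file path.
#' @export
save_spectrum_file <- function(record, path) {
  writeLines(write_spectrum_file(record), path, sep = "")
  invisible(path)
}

# case-insensitive header lookup
.hdr <- function(record, key, default = NULL) {
  i <- match(tolower(key), tolower(names(record$header)))
  if (is.na(i)) default else record$header[[i]]
}

# pick a named column (case-insensitive); unless `strict`, a sole
# non-wavelength column is accepted under any name
.column <- function(record, wanted, required = TRUE, strict = FALSE) {
  nm <- names(record$data)[-1]
  i <- match(tolower(wanted), tolower(nm))
  if (!is.na(i)) return(record$data[[nm[i]]])
  if (!strict && length(nm) == 1L) return(record$data[[nm]])
  if (required) {
    rlang::abort(sprintf("%s: no column named '%s'", record$source, wanted))
  }
  NULL
}

# ---- typed components from file records --------------------------------

record_to_dye <- function(record, id) {
  wl <- record$data$wavelength
  ec <- .hdr(record, "extinction_coefficient")
  qy <- .hdr(record, "quantum_yield")
  dye(id = id,
      absorption = spectrum(wl, .column(record, "absorption"),
                            kind = "absorption"),
      emission = spectrum(wl, .column(record, "emission"), kind = "emission"),
      ext_coeff = if (is.null(ec)) NA_real_ else as.numeric(ec),
      q_yield = if (is.null(qy)) NA_real_ else as.numeric(qy))
}

record_to_excitation <- function(record, id) {
  excitation(id, spectrum(record$data$wavelength,
                          .column(record, "intensity"), kind = "intensity"))
}

record_to_detector <- function(record, id) {
  detector(id, spectrum(record$data$wavelength,
                        .column(record, "qe"), kind = "qe"))
}

record_to_filter <- function(record, id) {
  wl <- record$data$wavelength
  tr <- .column(record, "transmission", required = FALSE, strict = TRUE)
  if (is.null(tr)) {
    rf <- .column(record, "reflection", required = FALSE, strict = TRUE)
    if (is.null(rf)) {
      # a single unnamed value column is taken as transmission
      tr <- .column(record, "transmission", required = FALSE)
      if (!is.null(tr)) {
        return(light_filter(id, spectrum(wl, tr, kind = "transmission")))
      }
    }
    if (is.null(rf)) {
      rlang::abort(sprintf(
        "%s: filter needs a transmission or reflection column", record$source))
    }
    return(light_filter(id, spc_complement(spectrum(wl, rf, kind = "reflection"))))
  }
  light_filter(id, spectrum(wl, tr, kind = "transmission"))
}

.record_makers <- list(dye = record_to_dye, excitation = record_to_excitation,
                       detector = record_to_detector, filter = record_to_filter)

# ---- collections -------------------------------------------------------

#' Load a lazy component collection
#'
#' The index file is a JSON array listing the collection's members, either as
#' plain filename strings (the id is the filename without extension) or as
#' objects `{"id": ..., "file": ...}`. Files are parsed only on first access
#' through [collection_get()]; parse failures surface then, naming the id.
#'
#' @param directory Directory holding the spectrum files.
#' @param index_file Path to the JSON index; default `<kind>s.json` inside
#'   `directory`.
#' @param kind One of `"dye"`, `"excitation"`, `"detector"`, `"filter"`.
#' @return An `lp_collection` object.
#' @export
load_collection <- function(directory, index_file = NULL,
                            kind = c("dye", "excitation", "detector", "filter")) {
  kind <- match.arg(kind)
  if (is.null(index_file)) {
    index_file <- file.path(directory, paste0(kind, "s.json"))
  }
  idx <- jsonlite::fromJSON(index_file, simplifyVector = FALSE)
  entries <- purrr::map(idx, function(e) {
    if (is.character(e)) {
      list(id = tools::file_path_sans_ext(basename(e)), file = e)
    } else {
      list(id = e$id %||% tools::file_path_sans_ext(basename(e$file)),
           file = e$file)
    }
  })
  ids <- purrr::map_chr(entries, "id")
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicate ids in %s: %s", index_file,
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  env <- new.env(parent = emptyenv())
  env$cache <- list()
  env$n_parsed <- 0L
  structure(list(kind = kind, directory = directory,
                 files = stats::setNames(purrr::map_chr(entries, "file"), ids),
                 env = env),
            class = "lp_collection")
}

#' Build a collection from in-memory components
#' @param components A list of components of one kind (dyes, filters, ...).
#' @param kind Component kind; inferred from the first element if missing.
#' @return An `lp_collection` with all members already materialised.
#' @export
collection_from_list <- function(components, kind = NULL) {
  if (is.null(kind)) {
    kind <- switch(class(components[[1]])[1],
                   lp_dye = "dye", lp_excitation = "excitation",
                   lp_detector = "detector", lp_filter = "filter",
                   rlang::abort("cannot infer component kind"))
  }
  ids <- purrr::map_chr(components, "id")
  if (anyDuplicated(ids)) rlang::abort("duplicate component ids")
  env <- new.env(parent = emptyenv())
  env$cache <- stats::setNames(components, ids)
  env$n_parsed <- 0L
  structure(list(kind = kind, directory = NULL,
                 files = stats::setNames(rep(NA_character_, length(ids)), ids),
                 env = env),
            class = "lp_collection")
}

#' @export
print.lp_collection <- function(x, ...) {
  cat(sprintf("<%s collection: %d entries>\n", x$kind, length(x$files)))
  invisible(x)
}

#' @export
length.lp_collection <- function(x) length(x$files)

#' Ids available in a collection
#' @param collection An `lp_collection`.
#' @return Character vector of component ids.
#' @export
collection_ids <- function(collection) names(collection$files)

#' Fetch (and lazily parse) a component by id
#' @param collection An `lp_collection`.
#' @param id Component id.
#' @return The typed component (dye, excitation, detector or filter).
#' @export
collection_get <- function(collection, id) {
  stopifnot(inherits(collection, "lp_collection"))
  if (!is.null(collection$env$cache[[id]])) return(collection$env$cache[[id]])
  if (!id %in% names(collection$files)) {
    rlang::abort(sprintf("no %s with id '%s' in collection",
                         collection$kind, id),
                 class = "lp_missing_id")
  }
  path <- file.path(collection$directory, collection$files[[id]])
  if (!file.exists(path)) {
    rlang::abort(sprintf("%s '%s': file '%s' not found",
                         collection$kind, id, path),
                 class = "lp_missing_file")
  }
  record <- read_spectrum_file(path)
  obj <- .record_makers[[collection$kind]](record, id)
  collection$env$cache[[id]] <- obj
  collection$env$n_parsed <- collection$env$n_parsed + 1L
  obj
}

# ---- setups ------------------------------------------------------------

#' Parse setup descriptions
#'
#' The setups document is a JSON array of objects
#' `{name, excitation, dye, detector, ex_path, em_path}` where each path is a
#' list of `{filter, mode}` objects with mode `"T"` (transmission) or `"R"`
#' (reflection). As a permissive fallback, plain strings of the form
#' `"FILTER-ID T"` are also accepted inside paths. The same filter may appear
#' in both paths with opposite modes, as a dichroic shared between the
#' excitation and emission arms does.
#'
#' @param text JSON text, a path to a JSON file, or parsed JSON.
#' @return A list of `lp_setup_description` objects.
#' @export
parse_setups <- function(text) {
  doc <- if (is.character(text)) {
    jsonlite::fromJSON(text, simplifyVector = FALSE)
  } else {
    text
  }
  parse_path <- function(p, where) {
    purrr::map(p, function(e) {
      if (is.character(e)) {
        parts <- strsplit(trimws(e), "\\s+")[[1]]
        e <- list(filter = paste(utils::head(parts, -1), collapse = " "),
                  mode = utils::tail(parts, 1))
      }
      mode <- toupper(e$mode %||% "T")
      if (!mode %in% c("T", "R")) {
        rlang::abort(sprintf("%s: unknown filter mode '%s'", where, e$mode))
      }
      if (!nzchar(e$filter %||% "")) {
        rlang::abort(sprintf("%s: empty filter id", where))
      }
      list(filter = e$filter, mode = mode)
    })
  }
  setups <- purrr::map(doc, function(s) {
    name <- s$name %||% rlang::abort("setup without a name")
    structure(list(name = name,
                   excitation = s$excitation, dye = s$dye,
                   detector = s$detector,
                   ex_path = parse_path(s$ex_path %||% list(), name),
                   em_path = parse_path(s$em_path %||% list(), name)),
              class = "lp_setup_description")
  })
  nm <- purrr::map_chr(setups, "name")
  if (anyDuplicated(nm)) {
    rlang::abort(sprintf("duplicate setup names: %s",
                         paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  setups
}

#' Read a setups file
#' @param path Path to the setups JSON document.
#' @return A list of `lp_setup_description` objects.
#' @export
read_setups <- function(path) parse_setups(paste(readLines(path, warn = FALSE),
                                                 collapse = "\n"))
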