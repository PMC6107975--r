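# Spectral plot of a setup evaluation. The transmitted fluorescence trace is
# drawn last, on top of everything else; excitation-path filters are not
# drawn as separate traces, the attenuated source already shows their effect.

# ordered traces for a report; transmitted deliberately last in the list so
# it is drawn topmost
.report_traces <- function(report, show_ex_filters = FALSE) {
  setup <- report$setup
  traces <- list("source (attenuated)" = report$attenuated_source,
                 "dye absorption" = resample(setup$dye$absorption),
                 "dye emission" = resample(setup$dye$emission))
  if (show_ex_filters && length(setup$ex_path) > 0L) {
    for (i in seq_along(setup$ex_path$filters)) {
      f <- setup$ex_path$filters[[i]]
      traces[[sprintf("ex: %s (%s)", f$id, setup$ex_path$modes[[i]])]] <-
        resample(.effective_spectrum(f, setup$ex_path$modes[[i]]))
    }
  }
  if (length(setup$em_path) > 0L) {
    for (i in seq_along(setup$em_path$filters)) {
      f <- setup$em_path$filters[[i]]
      traces[[sprintf("em: %s (%s)", f$id, setup$em_path$modes[[i]])]] <-
        resample(.effective_spectrum(f, setup$em_path$modes[[i]]))
    }
  }
  if (!is.null(setup$detector)) {
    traces[["detector qe"]] <- resample(setup$detector$qe)
  }
  traces[["transmitted"]] <- report$transmitted
  traces
}

#' Plot the spectra of an evaluated setup
#'
#' Draws the attenuated excitation source, dye absorption and emission, each
#' emission-path filter's effective spectrum, the detector quantum
#' efficiency, and — on top of all other traces — the transmitted
#' fluorescence spectrum. Intensity-like traces are scaled to unit peak so
#' all curves share one axis. The default window of 300--800 nm is display
#' only; every efficiency is computed over the full data range.
#'
#' @param object An `lp_report` from [light_report()].
#' @param range Length-2 numeric display window in nm (default `c(300, 800)`).
#' @param show_ex_filters Also draw excitation-path filter traces.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lp_report
#' @export
autoplot.lp_report <- function(object, range = c(300, 800),
                               show_ex_filters = FALSE, ...) {
  if (range[1] >= range[2]) rlang::abort("plot range must satisfy lo < hi")
  traces <- .report_traces(object, show_ex_filters = show_ex_filters)
  long <- dplyr::bind_rows(.id = "trace", purrr::map(traces, function(s) {
    v <- s$value
    if (spectrum_kind(s) == "intensity" && max(v) > 0) v <- v / max(v)
    tibble::tibble(wavelength = s$wavelength, value = v)
  }))
  long$trace <- factor(long$trace, levels = names(traces))
  transmitted <- long[long$trace == "transmitted", ]
  others <- long[long$trace != "transmitted", ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wavelength, y = .data$value,
                                     colour = .data$trace)) +
    ggplot2::geom_line(data = others, alpha = 0.8) +
    ggplot2::geom_line(data = transmitted, linewidth = 1.1) +
    ggplot2::coord_cartesian(xlim = range, ylim = c(0, 1.05)) +
    ggplot2::labs(
      x = "wavelength (nm)", y = "normalised value", colour = NULL,
      title = sprintf("ex %.1f%%  em %.1f%%  brightness %s",
                      100 * object$ex_eff, 100 * object$em_eff,
                      if (is.na(object$brightness)) "n/a"
                      else sprintf("%.2f", object$brightness))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.lp_report
#' @param report An `lp_report`.
#' @export
plot_light_path <- function(report, range = c(300, 800),
                            show_ex_filters = FALSE) {
  autoplot.lp_report(report, range = range, show_ex_filters = show_ex_filters)
}
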