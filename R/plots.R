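#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   geom_hline labs facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot an absorbance spectrum
#'
#' @param object A [uv_spectrum()].
#' @param components If `TRUE` and the spectrum carries per-source
#'   components (synthetic spectra do), draw one curve per source as well.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.uv_spectrum <- function(object, components = FALSE, ...) {
  p <- ggplot(as_tibble(unclass_spectrum(object)),
              aes(x = .data$wavelength_nm, y = .data$absorbance)) +
    geom_line(linewidth = 0.7) +
    labs(x = "wavelength (nm)", y = "absorbance (AU)",
         title = attr(object, "label")) +
    theme_minimal()
  comp <- spectrum_components(object)
  if (isTRUE(components) && !is.null(comp)) {
    long <- dplyr::bind_cols(wavelength_nm = object$wavelength_nm, comp) |>
      tidyr::pivot_longer(-"wavelength_nm",
                          names_to = "source", values_to = "absorbance")
    p <- p + geom_line(data = long, aes(color = .data$source),
                       linetype = "dashed", linewidth = 0.4)
  }
  p
}

#' Plot a calibration line with its standards
#'
#' @param object A [fit_calibration()] result (must carry its data).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.uv_calibration <- function(object, ...) {
  if (is.null(object$data)) {
    abort("This calibration line carries no raw standards to plot.")
  }
  ggplot(object$data, aes(x = .data$concentration, y = .data$absorbance)) +
    geom_point(size = 2) +
    geom_abline(intercept = object$intercept, slope = object$slope,
                color = "steelblue") +
    labs(x = "concentration (mmol/L)", y = "absorbance (AU)",
         title = paste0(object$analyte %||% "analyte",
                        if (!is.na(object$wavelength))
                          paste0(" @ ", object$wavelength, " nm") else ""),
         subtitle = sprintf("A = %.4g + %.4g C   (r² = %.4f)",
                            object$intercept, object$slope,
                            object$r_squared)) +
    theme_minimal()
}

#' Plot a recovery table
#'
#' Per-record recoveries by analyte with the 100% reference line.
#'
#' @param object A [recovery_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.recovery_table <- function(object, ...) {
  df <- as_tibble(object)
  df$record <- seq_len(nrow(df))
  ggplot(df, aes(x = factor(.data$record), y = .data$recovery,
                 color = .data$analyte)) +
    geom_hline(yintercept = 100, linetype = "dashed", color = "grey50") +
    geom_point(size = 3) +
    labs(x = "record", y = "recovery (%)", color = "analyte") +
    theme_minimal()
}

#' Plot a simulated hydrolysate time series
#'
#' Concentration of glucose, HMF and LA against reaction time for a
#' [simulate_hydrolysate_series()] result.
#'
#' @param series Tibble with columns `time_min`, `glucose`, `HMF`, `LA`.
#' @return A ggplot.
#' @export
plot_hydrolysate_series <- function(series) {
  long <- tidyr::pivot_longer(series, -"time_min",
                              names_to = "species", values_to = "mmol_per_l")
  ggplot(long, aes(x = .data$time_min, y = .data$mmol_per_l,
                   color = .data$species)) +
    geom_line(linewidth = 0.8) +
    labs(x = "reaction time (min)", y = "concentration (mmol/L)",
         color = NULL) +
    theme_minimal()
}
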