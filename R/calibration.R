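#' Fit a Beer's-law calibration line
#'
#' Ordinary least squares of absorbance on concentration, with intercept.
#' For a 1 cm path length the slope is the analyte's molar absorptivity in
#' mmol^-1.L.cm^-1. The reported intercept uncertainty is the standard error
#' of the intercept, which feeds the limit of quantitation ([loq()]).
#'
#' @param data A data frame with numeric columns `concentration` (mmol/L,
#'   >= 0) and `absorbance` (AU); at least 3 points with non-constant
#'   concentrations.
#' @param analyte Optional analyte identifier (e.g. `"HMF"`).
#' @param wavelength Optional measurement wavelength in nm.
#' @return An object of class `uv_calibration` with components `analyte`,
#'   `wavelength`, `intercept`, `slope`, `intercept_se`, `slope_se`,
#'   `r_squared`, `n`, the underlying `lm` fit, and the data. Supports
#'   [tidy()], [glance()], [loq()], [molar_absorptivity()] and `autoplot()`.
#' @examples
#' cal <- data.frame(concentration = c(0.019, 0.037, 0.056, 0.075, 0.093),
#'                   absorbance    = 0.006 + 22.7 * c(0.019, 0.037, 0.056, 0.075, 0.093))
#' fit <- fit_calibration(cal, analyte = "HMF", wavelength = 284)
#' glance(fit)
#' @export
fit_calibration <- function(data, analyte = NULL, wavelength = NA_real_) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  missing_cols <- setdiff(c("concentration", "absorbance"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  conc <- data$concentration
  ab <- data$absorbance
  if (anyNA(conc) || anyNA(ab)) abort("Calibration data contain missing values.")
  if (length(conc) < 3) {
    abort("At least 3 calibration points are required.")
  }
  if (any(conc < 0)) abort("Concentrations must be >= 0.")
  if (diff(range(conc)) == 0) {
    abort("Degenerate design: all concentrations are equal.")
  }
  fit <- stats::lm(absorbance ~ concentration,
                   data = data.frame(concentration = conc, absorbance = ab))
  # summary.lm warns on noiseless (exactly collinear) standards; that case is
  # legitimate here (synthetic round trips), so muffle just that warning
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  cf <- sm$coefficients
  new_uv_calibration(
    analyte = analyte,
    wavelength = wavelength,
    intercept = unname(cf["(Intercept)", "Estimate"]),
    slope = unname(cf["concentration", "Estimate"]),
    intercept_se = unname(cf["(Intercept)", "Std. Error"]),
    slope_se = unname(cf["concentration", "Std. Error"]),
    r_squared = sm$r.squared,
    n = length(conc),
    fit = fit,
    data = as_tibble(data[, c("concentration", "absorbance")])
  )
}

#' Build a calibration line from published coefficients
#'
#' Constructs a `uv_calibration` directly from a slope, intercept and their
#' standard errors, e.g. when the line is quoted in a report rather than
#' refitted from raw standards. Used by [method_defaults()] for the four
#' reference lines of the HMF/LA method.
#'
#' @param analyte Analyte identifier.
#' @param wavelength Wavelength in nm.
#' @param slope Slope in AU.L/mmol (molar absorptivity at 1 cm path).
#' @param intercept Intercept in AU.
#' @param intercept_se,slope_se Standard errors (>= 0).
#' @param r_squared Coefficient of determination, if known.
#' @param n Number of calibration points, if known.
#' @return A `uv_calibration` object (without an underlying `lm` fit).
#' @export
calibration_line <- function(analyte, wavelength, slope, intercept,
                             intercept_se = 0, slope_se = 0,
                             r_squared = NA_real_, n = NA_integer_) {
  new_uv_calibration(analyte = analyte, wavelength = wavelength,
                     intercept = intercept, slope = slope,
                     intercept_se = intercept_se, slope_se = slope_se,
                     r_squared = r_squared, n = n,
                     fit = NULL, data = NULL)
}

new_uv_calibration <- function(analyte, wavelength, intercept, slope,
                               intercept_se, slope_se, r_squared, n,
                               fit, data) {
  if (!is.finite(slope) || slope == 0) {
    abort("Calibration slope must be finite and nonzero.")
  }
  if (intercept_se < 0 || slope_se < 0) {
    abort("Standard errors must be >= 0.")
  }
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1 + 1e-12)) {
    abort("`r_squared` must lie in [0, 1].")
  }
  structure(
    list(analyte = analyte, wavelength = wavelength,
         intercept = intercept, slope = slope,
         intercept_se = intercept_se, slope_se = slope_se,
         r_squared = min(r_squared, 1), n = n, fit = fit, data = data),
    class = "uv_calibration"
  )
}

#' @export
print.uv_calibration <- function(x, digits = 4, ...) {
  id <- paste0(x$analyte %||% "analyte",
               if (!is.na(x$wavelength)) paste0(" @ ", x$wavelength, " nm") else "")
  cat("<uv_calibration> ", id, "\n", sep = "")
  cat(sprintf("  A = %s(+/-%s) + %s(+/-%s) C",
              signif(x$intercept, digits), signif(x$intercept_se, digits),
              signif(x$slope, digits), signif(x$slope_se, digits)))
  cat(sprintf("   (n = %s, r^2 = %s)\n",
              if (is.na(x$n)) "?" else x$n,
              if (is.na(x$r_squared)) "?" else signif(x$r_squared, digits)))
  lq <- tryCatch(loq(x), error = function(e) NA_real_)
  if (!is.na(lq)) cat(sprintf("  LOQ = %s mmol/L\n", signif(lq, 3)))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `uv_calibration` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.uv_calibration <- function(x, ...) {
  tibble(term = c("(Intercept)", "concentration"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$intercept_se, x$slope_se))
}

#' @rdname fit_calibration
#' @exportS3Method generics::glance
glance.uv_calibration <- function(x, ...) {
  tibble(analyte = x$analyte %||% NA_character_,
         wavelength = x$wavelength,
         slope = x$slope,
         intercept = x$intercept,
         slope_se = x$slope_se,
         intercept_se = x$intercept_se,
         r.squared = x$r_squared,
         n = as.integer(x$n),
         loq = tryCatch(loq(x), error = function(e) NA_real_))
}

#' Limit of quantitation of a calibration line
#'
#' LOQ = (a + 10 * |da|) / s, where a is the (signed) intercept, da its
#' standard error and s the slope. The signed intercept is used exactly as
#' the defining formula is written; for the reference HMF and LA lines,
#' using |a| instead changes nothing after rounding to the printed precision.
#'
#' @param x A `uv_calibration` object, or the numeric intercept `a`.
#' @param ... Passed to methods.
#' @return LOQ in mmol/L (full precision; round for display).
#' @examples
#' loq(-0.0055, 0.021, 12.38)  # 0.0165... -> 0.017 mmol/L
#' @export
loq <- function(x, ...) UseMethod("loq")

#' @rdname loq
#' @export
loq.uv_calibration <- function(x, ...) {
  loq_value(x$intercept, x$intercept_se, x$slope)
}

#' @rdname loq
#' @param intercept_se Standard error of the intercept (AU, >= 0).
#' @param slope Slope (AU.L/mmol, > 0).
#' @export
loq.numeric <- function(x, intercept_se, slope, ...) {
  loq_value(x, intercept_se, slope)
}

loq_value <- function(intercept, intercept_se, slope) {
  if (!is.finite(slope) || slope <= 0) {
    abort("LOQ requires a positive slope.")
  }
  (intercept + 10 * abs(intercept_se)) / slope
}

#' Molar absorptivity from a calibration slope
#'
#' By Beer's law A = eps * l * C, so eps = slope / path length.
#'
#' @param x A `uv_calibration` object or a numeric slope (AU.L/mmol).
#' @param path_length Path length in cm (> 0).
#' @return Molar absorptivity in mmol^-1.L.cm^-1.
#' @export
molar_absorptivity <- function(x, path_length = 1) {
  if (!is.numeric(path_length) || path_length <= 0) {
    abort("`path_length` must be > 0.")
  }
  slope <- if (inherits(x, "uv_calibration")) x$slope else x
  slope / path_length
}
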