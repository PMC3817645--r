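#' Reference constants of the dual-wavelength HMF/LA method
#'
#' A versioned profile of the published method constants so analyses and
#' tests can pin them: the four Beer's-law calibration lines (one per
#' analyte per wavelength), the molar absorptivity matrix at 266/284 nm,
#' the charcoal correction coefficients, the limits of quantitation, the
#' standard concentration series used for calibration, and the analytes'
#' molar masses.
#'
#' @details
#' The calibration lines (absorbance in AU, concentration in mmol/L,
#' standard errors in parentheses) are:
#' \itemize{
#'   \item HMF, 266 nm: A = -0.0055(0.021) + 12.38(0.37) C, r^2 = 0.9954
#'   \item HMF, 284 nm: A =  0.006(0.029)  + 22.7(0.5)   C, r^2 = 0.9975
#'   \item LA,  266 nm: A =  0.0096(0.0077) + 0.023(0.0002) C, r^2 = 0.9996
#'   \item LA,  284 nm: A =  0.0075(0.0058) + 0.014(0.0001) C, r^2 = 0.9995
#' }
#' The correction coefficients K (absorbance before / after charcoal
#' treatment, at each analyte's read-out wavelength) are 69.3 for HMF at
#' 284 nm and 1.62 for LA at 266 nm. K_HMF = 69.3 implies ~98.6% of the
#' HMF is adsorbed, which leaves very little signal; the value is used at
#' face value as the published constant, but treat HMF contents after
#' charcoal correction with caution.
#'
#' @return A named list with elements `wavelengths`, `analytes`, `epsilon`
#'   (an [absorptivity_matrix()]), `k`, `loq` (mmol/L), `molar_mass`
#'   (g/mol), `standards` (calibration concentrations, mmol/L),
#'   `charcoal_dosage` (g/mL for complete byproduct removal) and
#'   `calibration` (list of [calibration_line()]s keyed `"HMF_266"` etc.).
#' @examples
#' defs <- method_defaults()
#' loq(defs$calibration$HMF_266)
#' @export
method_defaults <- function() {
  list(
    wavelengths = c(266, 284),
    analytes = c("HMF", "LA"),
    epsilon = absorptivity_matrix(),
    k = c(HMF = 69.3, LA = 1.62),
    loq = c(HMF = 0.017, LA = 4.68),
    molar_mass = c(HMF = 126.11, LA = 116.12),
    standards = list(
      HMF = c(0.019, 0.037, 0.056, 0.075, 0.093),
      LA = c(20.25, 29.80, 39.00, 47.86, 64.66)
    ),
    charcoal_dosage = 0.1,
    calibration = list(
      HMF_266 = calibration_line("HMF", 266, slope = 12.38, intercept = -0.0055,
                                 intercept_se = 0.021, slope_se = 0.37,
                                 r_squared = 0.9954, n = 6L),
      HMF_284 = calibration_line("HMF", 284, slope = 22.7, intercept = 0.006,
                                 intercept_se = 0.029, slope_se = 0.5,
                                 r_squared = 0.9975, n = 6L),
      LA_266 = calibration_line("LA", 266, slope = 0.023, intercept = 0.0096,
                                intercept_se = 0.0077, slope_se = 0.0002,
                                r_squared = 0.9996, n = 6L),
      LA_284 = calibration_line("LA", 284, slope = 0.014, intercept = 0.0075,
                                intercept_se = 0.0058, slope_se = 0.0001,
                                r_squared = 0.9995, n = 6L)
    )
  )
}
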