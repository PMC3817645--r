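#' Molar absorptivity matrix for the two-wavelength system
#'
#' The 2x2 table of molar absorptivities eps\[wavelength, analyte\] that
#' defines the two-component Beer's-law system. Defaults are the reference
#' values for HMF and LA at 266/284 nm obtained from their calibration
#' lines at 1 cm path length.
#'
#' @param hmf Absorptivities of HMF at `wavelengths` (mmol^-1.L.cm^-1).
#' @param la Absorptivities of LA at `wavelengths`.
#' @param wavelengths Ordered pair of wavelengths in nm.
#' @param analytes Ordered pair of analyte identifiers.
#' @return A 2x2 numeric matrix (rows = wavelengths, cols = analytes) of
#'   class `absorptivity_matrix`.
#' @examples
#' absorptivity_matrix()
#' @export
absorptivity_matrix <- function(hmf = c(12.38, 22.7), la = c(0.023, 0.014),
                                wavelengths = c(266, 284),
                                analytes = c("HMF", "LA")) {
  if (length(hmf) != 2 || length(la) != 2 || length(wavelengths) != 2) {
    abort("Exactly two wavelengths and two absorptivities per analyte are required.")
  }
  if (any(c(hmf, la) < 0)) abort("Absorptivities must be >= 0.")
  if (wavelengths[1] == wavelengths[2]) abort("Wavelengths must be distinct.")
  E <- cbind(hmf, la)
  dimnames(E) <- list(as.character(wavelengths), analytes)
  check_solvable(E)
  structure(E, class = c("absorptivity_matrix", "matrix", "array"))
}

check_solvable <- function(E) {
  d <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  if (abs(d) <= 1e-12 * max(abs(E))^2) {
    abort("Singular absorptivity matrix: the two-component system is not solvable.")
  }
  invisible(d)
}

#' Charcoal correction coefficient for an analyte
#'
#' Activated charcoal removes the colored hydrolysis byproducts but also
#' adsorbs part of the analytes. The correction coefficient
#' K = A_before / A_after at the analyte's read-out wavelength compensates
#' for that loss. K >= 1 under pure adsorption; a ratio below 1 (treatment
#' apparently added absorbance) is returned with a warning.
#'
#' @param before,after [uv_spectrum()]s of the same standard measured before
#'   and after charcoal treatment.
#' @param wavelength Read-out wavelength in nm (284 for HMF, 266 for LA).
#' @return The dimensionless coefficient K.
#' @examples
#' b <- uv_spectrum(data.frame(wavelength_nm = c(260, 290), absorbance = c(0.81, 0.81)))
#' a <- uv_spectrum(data.frame(wavelength_nm = c(260, 290), absorbance = c(0.50, 0.50)))
#' correction_coefficient(b, a, 266)  # 1.62
#' @export
correction_coefficient <- function(before, after, wavelength) {
  a_b <- absorbance_at(before, wavelength)
  a_a <- absorbance_at(after, wavelength)
  if (a_a <= 0) {
    abort("Post-treatment absorbance is <= 0; correction coefficient undefined.")
  }
  k <- a_b / a_a
  if (k < 1) {
    warn(sprintf("Correction coefficient %.4g < 1 at %g nm: treatment appears to have added absorbance.",
                 k, wavelength))
  }
  k
}

#' Solve the two-component Beer's-law system
#'
#' Given mixture absorbances at the two wavelengths, solves
#' `A_lambda = l * sum_analyte eps[lambda, analyte] * C_analyte` exactly for
#' the two concentrations. Vectorised over absorbance pairs. Negative
#' solutions (possible with measurement noise near the LOQ) are returned
#' unclamped; [quantify_sample()] clamps and flags them.
#'
#' @param a266,a284 Absorbances (AU) at the first and second wavelength of
#'   `eps` (266 and 284 nm by default); equal-length vectors.
#' @param eps An [absorptivity_matrix()].
#' @param path_length Path length in cm.
#' @return A tibble with one concentration column (mmol/L) per analyte and
#'   one row per absorbance pair.
#' @examples
#' solve_two_component(1.309, 1.555)  # recovers C_HMF = 0.05, C_LA = 30
#' @export
solve_two_component <- function(a266, a284, eps = absorptivity_matrix(),
                                path_length = 1) {
  if (length(a266) != length(a284)) {
    abort("`a266` and `a284` must have the same length.")
  }
  if (!is.matrix(eps) || !all(dim(eps) == c(2, 2))) {
    abort("`eps` must be a 2x2 absorptivity matrix.")
  }
  if (path_length <= 0) abort("`path_length` must be > 0.")
  check_solvable(eps)
  Einv <- solve(unclass(eps) * path_length)
  C <- Einv %*% rbind(a266, a284)        # 2 x n, rows = analytes
  analytes <- colnames(eps) %||% c("C1", "C2")
  out <- as_tibble(t(C), .name_repair = "minimal")
  names(out) <- analytes
  out
}

#' Convert a solved concentration to hydrolysate content
#'
#' W = C * M * K * R: the concentration measured in the charcoal-treated,
#' diluted solution (mmol/L) times the molar mass (g/mol) gives mg/L, scaled
#' back up by the charcoal correction coefficient K and dilution factor R to
#' the content of the original hydrolysate.
#'
#' @param concentration Solved concentration, mmol/L (>= 0).
#' @param molar_mass Molar mass, g/mol.
#' @param k Charcoal correction coefficient (dimensionless).
#' @param dilution Dilution factor R (dimensionless).
#' @return Content in mg/L; vectorised over all arguments.
#' @export
contents <- function(concentration, molar_mass, k = 1, dilution = 1) {
  if (any(c(concentration, molar_mass, k, dilution) < 0)) {
    abort("All inputs to `contents()` must be >= 0.")
  }
  concentration * molar_mass * k * dilution
}

#' Quantify HMF and LA in a charcoal-treated hydrolysate spectrum
#'
#' The full dual-wavelength read-out: absorbances at 266 and 284 nm are
#' interpolated from the treated spectrum, the two-component Beer's-law
#' system is solved, negative concentrations are clamped to zero (flagged),
#' concentrations below the limit of quantitation are flagged, and contents
#' in the original hydrolysate are computed as W = C * M * K * R using the
#' spectrum's dilution factor R.
#'
#' @param treated A [uv_spectrum()] of the charcoal-treated sample, covering
#'   both read-out wavelengths.
#' @param eps An [absorptivity_matrix()].
#' @param k Named charcoal correction coefficients per analyte
#'   (before/after absorbance ratio, >= 1).
#' @param molar_mass Named molar masses per analyte, g/mol.
#' @param loq Optional named limits of quantitation per analyte, mmol/L.
#' @return A tibble of class `uv_quant`, one row per analyte, with columns
#'   `analyte`, `concentration` (mmol/L, in the treated, diluted solution),
#'   `content` (mg/L in the original hydrolysate), `k`, `molar_mass`,
#'   `below_loq` and `negative_clamped`. The measured absorbances, dilution
#'   factor and path length are attached as attributes.
#' @examples
#' defs <- method_defaults()
#' s <- uv_spectrum(data.frame(wavelength_nm = c(266, 284),
#'                             absorbance    = c(1.309, 1.555)))
#' quantify_sample(s, k = c(HMF = 1, LA = 1))
#' @export
quantify_sample <- function(treated, eps = absorptivity_matrix(),
                            k = method_defaults()$k,
                            molar_mass = method_defaults()$molar_mass,
                            loq = NULL) {
  stopifnot(inherits(treated, "uv_spectrum"))
  wavelengths <- as.numeric(rownames(eps))
  analytes <- colnames(eps)
  a <- absorbance_at(treated, wavelengths)
  conc <- solve_two_component(a[1], a[2], eps = eps,
                              path_length = path_length(treated))
  conc <- as.numeric(conc[1, analytes])
  k <- constants_for(k, analytes, "k")
  molar_mass <- constants_for(molar_mass, analytes, "molar_mass")
  negative <- conc < 0
  conc[negative] <- 0
  below <- if (is.null(loq)) rep(FALSE, 2) else {
    conc < constants_for(loq, analytes, "loq")
  }
  R <- dilution_factor(treated)
  out <- tibble(
    analyte = analytes,
    concentration = unname(conc),
    content = unname(contents(conc, molar_mass, k, R)),
    k = unname(k),
    molar_mass = unname(molar_mass),
    below_loq = unname(below),
    negative_clamped = negative
  )
  structure(out,
            class = c("uv_quant", class(out)),
            absorbance = setNames(a, wavelengths),
            dilution_factor = R,
            path_length = path_length(treated))
}

constants_for <- function(x, analytes, what) {
  if (is.null(names(x))) {
    if (length(x) == 1) return(setNames(rep(x, length(analytes)), analytes))
    if (length(x) == length(analytes)) return(setNames(x, analytes))
    abort(sprintf("`%s` must be named by analyte or have length 1.", what))
  }
  missing_an <- setdiff(analytes, names(x))
  if (length(missing_an) > 0) {
    abort(sprintf("`%s` is missing value(s) for: %s.",
                  what, paste(missing_an, collapse = ", ")))
  }
  x[analytes]
}

#' @export
print.uv_quant <- function(x, ...) {
  a <- attr(x, "absorbance")
  cat("<uv_quant> dual-wavelength determination\n")
  cat(sprintf("  A(%s nm) = %.4g, A(%s nm) = %.4g | path %g cm | dilution x%g\n",
              names(a)[1], a[1], names(a)[2], a[2],
              attr(x, "path_length"), attr(x, "dilution_factor")))
  y <- x
  class(y) <- setdiff(class(y), "uv_quant")
  print(y, ...)
  invisible(x)
}
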