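#' Synthetic-spectra generator configuration
#'
#' Forward model standing in for the spectrophotometer: each analyte absorbs
#' as a Gaussian band, hydrolysis byproducts contribute a broad interferent
#' band in the 350-450 nm window, measurement noise is additive Gaussian
#' (truncated so absorbance stays >= 0), and charcoal treatment removes the
#' interferent while attenuating the analytes by their correction
#' coefficients.
#'
#' @details
#' Default band widths are chosen so the Gaussians reproduce both published
#' absorptivities per analyte: the HMF band (center 284 nm, peak 22.7)
#' passes through 12.38 at 266 nm with sigma ~= 16.35 nm, and the LA band
#' (center 266 nm, peak 0.023) passes through 0.014 at 284 nm with sigma
#' ~= 18.06 nm — the unique two-parameter Gaussian through each pair of
#' constraints. The byproduct band defaults to center 400 nm, sigma 30 nm
#' (covering 350-450 nm) and amplitude 0.5 AU, a visibly "obvious"
#' interference on the scale of the analyte signals.
#'
#' The consecutive first-order kinetics glucose -> HMF -> LA exist only to
#' drive demonstrations and stress tests; rates are not fitted to any real
#' hydrolysis run. Defaults k1 = 0.08/min and k2 = 0.018/min put the HMF
#' maximum near 24 min; g0 = 333 mmol/L corresponds to 3 g glucose in 50 mL.
#'
#' @param bands Named list (per analyte) of lists with `center` (nm),
#'   `width` (Gaussian sigma, nm) and `peak` (mmol^-1.L.cm^-1).
#' @param byproduct List with `center`, `width` (nm) and `amplitude` (AU)
#'   of the interferent band; set `amplitude = 0` for clean standards.
#' @param noise_sd Additive measurement noise standard deviation, AU.
#' @param k Named charcoal correction coefficients per analyte (>= 1).
#' @param charcoal_dosage Dosage applied by [charcoal_treat()], g charcoal
#'   per mL sample.
#' @param full_dosage Dosage at and above which the interferent is removed
#'   completely (g/mL).
#' @param kinetics List with rates `k1`, `k2` (1/min) and initial glucose
#'   `g0` (mmol/L) for [simulate_hydrolysate_series()].
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(bands = default_bands(),
                             byproduct = list(center = 400, width = 30, amplitude = 0.5),
                             noise_sd = 0,
                             k = c(HMF = 69.3, LA = 1.62),
                             charcoal_dosage = 0.1,
                             full_dosage = 0.1,
                             kinetics = list(k1 = 0.08, k2 = 0.018, g0 = 333),
                             seed = NULL) {
  stopifnot(noise_sd >= 0, charcoal_dosage >= 0, full_dosage > 0)
  if (any(k < 1)) abort("Correction coefficients `k` must be >= 1.")
  for (b in bands) {
    if (b$width <= 0 || b$peak <= 0) abort("Band widths and peaks must be > 0.")
  }
  structure(list(bands = bands, byproduct = byproduct, noise_sd = noise_sd,
                 k = k, charcoal_dosage = charcoal_dosage,
                 full_dosage = full_dosage, kinetics = kinetics, seed = seed),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_bands <- function() {
  list(
    HMF = list(center = 284, peak = 22.7,
               width = band_width_from_ratio(284 - 266, 12.38 / 22.7)),
    LA = list(center = 266, peak = 0.023,
              width = band_width_from_ratio(284 - 266, 0.014 / 0.023))
  )
}

#' Gaussian band width from a two-point absorptivity constraint
#'
#' Solves `exp(-delta^2 / (2 sigma^2)) = ratio` for sigma: the width of the
#' Gaussian band whose absorptivity falls to `ratio` times its peak at
#' `delta` nm from the center.
#'
#' @param delta Offset from the band center, nm.
#' @param ratio Off-peak to peak absorptivity ratio, in (0, 1).
#' @return The Gaussian sigma in nm.
#' @export
band_width_from_ratio <- function(delta, ratio) {
  stopifnot(ratio > 0, ratio < 1, delta != 0)
  sqrt(delta^2 / (2 * log(1 / ratio)))
}

band_absorptivity <- function(band, wavelength) {
  band$peak * exp(-(wavelength - band$center)^2 / (2 * band$width^2))
}

#' Render a synthetic absorbance spectrum
#'
#' Beer's-law forward model: A(lambda) = l * sum_analyte
#' eps_analyte(lambda) * C_analyte + byproduct(lambda) + noise, truncated
#' at zero from below. The per-source contributions are attached as the
#' spectrum's `components` so [charcoal_treat()] can act on each source.
#'
#' @param concentrations Named vector of analyte concentrations, mmol/L
#'   (names matching `config$bands`).
#' @param config A [synthetic_config()].
#' @param grid Wavelength grid, nm (strictly increasing, length >= 2).
#' @param path_length,dilution_factor,label Passed to [uv_spectrum()].
#' @return A [uv_spectrum()] with a `components` attribute.
#' @examples
#' cfg <- synthetic_config(noise_sd = 0)
#' s <- render_spectrum(c(HMF = 0.05, LA = 0), cfg)
#' absorbance_at(s, 284)  # 22.7 * 0.05 + byproduct tail = ~1.135
#' @export
render_spectrum <- function(concentrations, config = synthetic_config(),
                            grid = seq(200, 600, by = 1),
                            path_length = 1, dilution_factor = 1,
                            label = "synthetic") {
  if (length(grid) < 2) abort("`grid` must contain at least 2 wavelengths.")
  if (any(concentrations < 0)) abort("Concentrations must be >= 0.")
  analytes <- names(config$bands)
  conc <- constants_for(concentrations, analytes, "concentrations")
  comp <- purrr::map(analytes, function(an) {
    band_absorptivity(config$bands[[an]], grid) * conc[[an]] * path_length
  })
  names(comp) <- analytes
  bp <- config$byproduct
  comp$byproduct <- bp$amplitude * exp(-(grid - bp$center)^2 / (2 * bp$width^2))
  clean <- Reduce(`+`, comp)
  noisy <- if (config$noise_sd > 0) {
    eps <- with_config_seed(config, rnorm(length(grid), 0, config$noise_sd))
    pmax(clean + eps, 0)
  } else clean
  comp$noise <- noisy - clean  # after truncation, so components always sum to A
  uv_spectrum(tibble(wavelength_nm = grid, absorbance = noisy),
              path_length = path_length, dilution_factor = dilution_factor,
              label = label, components = as_tibble(comp))
}

with_config_seed <- function(config, expr) {
  if (is.null(config$seed)) expr else withr::with_seed(config$seed, expr)
}

#' Apply the charcoal-treatment model to a synthetic spectrum
#'
#' The interferent (byproduct) component is scaled by
#' `max(0, 1 - dosage / full_dosage)` — it vanishes at and above the
#' complete-removal dosage of 0.1 g/mL — while each analyte component is
#' attenuated linearly in dosage from factor 1 (untreated) down to 1/K at
#' full dosage, K being that analyte's correction coefficient. Dosage 0 is
#' the identity.
#'
#' @param s A [uv_spectrum()] produced by [render_spectrum()] (it must
#'   carry per-source components).
#' @param config A [synthetic_config()].
#' @param dosage Charcoal dosage, g/mL; defaults to `config$charcoal_dosage`.
#' @return The treated [uv_spectrum()], components updated.
#' @export
charcoal_treat <- function(s, config = synthetic_config(),
                           dosage = config$charcoal_dosage) {
  stopifnot(inherits(s, "uv_spectrum"), dosage >= 0)
  comp <- spectrum_components(s)
  if (is.null(comp)) {
    abort("Spectrum carries no per-source components; charcoal_treat() models treatment of rendered synthetic spectra.")
  }
  frac <- min(dosage / config$full_dosage, 1)  # fraction of full treatment
  out <- comp
  if ("byproduct" %in% names(out)) {
    out$byproduct <- out$byproduct * (1 - frac)
  }
  for (an in names(config$bands)) {
    if (an %in% names(out)) {
      factor_an <- 1 + frac * (1 / config$k[[an]] - 1)
      out[[an]] <- out[[an]] * factor_an
    }
  }
  total <- pmax(Reduce(`+`, out[names(out) != "noise"]) +
                  (out$noise %||% 0), 0)
  uv_spectrum(tibble(wavelength_nm = s$wavelength_nm, absorbance = total),
              path_length = path_length(s),
              dilution_factor = dilution_factor(s),
              label = paste0(attr(s, "label") %||% "spectrum",
                             sprintf(" + charcoal %.3g g/mL", dosage)),
              components = out)
}

#' Generate a synthetic calibration table
#'
#' Absorbances `intercept + slope * C + noise` at the given standard
#' concentrations, reproducible under a seed. Defaults to the standard
#' concentration series of the reference method for known analytes.
#'
#' @param analyte Analyte identifier (`"HMF"` or `"LA"` select the default
#'   standards).
#' @param slope,intercept Generating line (AU.L/mmol, AU).
#' @param concentrations Standard concentrations, mmol/L.
#' @param noise_sd Additive Gaussian noise sd, AU.
#' @param seed Integer seed.
#' @return A tibble with columns `concentration` and `absorbance`, ready
#'   for [fit_calibration()].
#' @examples
#' make_calibration_set("HMF", slope = 22.7, intercept = 0.006) |>
#'   fit_calibration(analyte = "HMF", wavelength = 284)
#' @export
make_calibration_set <- function(analyte, slope, intercept = 0,
                                 concentrations = NULL, noise_sd = 0,
                                 seed = NULL) {
  if (is.null(concentrations)) {
    std <- method_defaults()$standards
    if (!analyte %in% names(std)) {
      abort("No default standards for this analyte; supply `concentrations`.")
    }
    concentrations <- std[[analyte]]
  }
  if (any(concentrations < 0)) abort("Concentrations must be >= 0.")
  a <- intercept + slope * concentrations
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) rnorm(length(a), 0, noise_sd) else {
      withr::with_seed(seed, rnorm(length(a), 0, noise_sd))
    }
    a <- a + noise
  }
  tibble(concentration = concentrations, absorbance = a)
}

#' Simulate hydrolysate composition over reaction time
#'
#' Closed-form consecutive first-order kinetics glucose -> HMF -> LA:
#' glucose(t) = g0 exp(-k1 t); HMF(t) = g0 k1/(k2 - k1) (exp(-k1 t) -
#' exp(-k2 t)) (limiting form g0 k1 t exp(-k1 t) when k1 = k2);
#' LA(t) = g0 - glucose(t) - HMF(t), so mass is conserved exactly. This is
#' a demonstration driver, not a fitted model of any real hydrolysis run.
#'
#' @param config A [synthetic_config()]; rates and g0 from `config$kinetics`.
#' @param times Reaction times, minutes (>= 0).
#' @return A tibble with columns `time_min`, `glucose`, `HMF`, `LA`
#'   (mmol/L).
#' @examples
#' simulate_hydrolysate_series(times = c(0, 10, 24, 60))
#' @export
simulate_hydrolysate_series <- function(config = synthetic_config(),
                                        times = seq(0, 120, by = 1)) {
  kin <- config$kinetics
  k1 <- kin$k1; k2 <- kin$k2; g0 <- kin$g0
  if (k1 <= 0 || k2 <= 0) abort("Kinetic rates k1, k2 must be > 0.")
  if (any(times < 0)) abort("`times` must be >= 0.")
  glucose <- g0 * exp(-k1 * times)
  hmf <- if (k1 == k2) {
    g0 * k1 * times * exp(-k1 * times)
  } else {
    g0 * k1 / (k2 - k1) * (exp(-k1 * times) - exp(-k2 * times))
  }
  hmf <- hmf + 0  # normalise IEEE negative zero at t = 0
  tibble(time_min = times, glucose = glucose, HMF = hmf,
         LA = g0 - glucose - hmf)
}

#' Time of the HMF maximum in the kinetics model
#'
#' For k1 != k2 the intermediate peaks at t* = ln(k1/k2) / (k1 - k2);
#' for k1 = k2, at 1/k1.
#'
#' @inheritParams simulate_hydrolysate_series
#' @return Peak time in minutes.
#' @export
hmf_peak_time <- function(config = synthetic_config()) {
  kin <- config$kinetics
  if (kin$k1 == kin$k2) 1 / kin$k1 else log(kin$k1 / kin$k2) / (kin$k1 - kin$k2)
}
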