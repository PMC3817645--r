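test_that("default Gaussian bands hit both published absorptivities per analyte", {
  bands <- default_bands()
  eps_at <- function(b, wl) b$peak * exp(-(wl - b$center)^2 / (2 * b$width^2))
  # each band is constrained by its peak value and its value 18 nm away
  expect_equal(eps_at(bands$HMF, 284), 22.7)
  expect_equal(eps_at(bands$HMF, 266), 12.38, tolerance = 1e-2 / 12.38)
  expect_equal(eps_at(bands$LA, 266), 0.023)
  expect_equal(eps_at(bands$LA, 284), 0.014, tolerance = 1e-2 / 0.014 * 0.0001)
  expect_equal(bands$HMF$width, 16.346, tolerance = 1e-3)
  expect_equal(bands$LA$width, 18.064, tolerance = 1e-3)
})

test_that("render_spectrum is the Beer's-law forward model", {
  cfg0 <- synthetic_config(noise_sd = 0,
                           byproduct = list(center = 400, width = 30, amplitude = 0))
  s <- render_spectrum(c(HMF = 0.05, LA = 0), cfg0)
  expect_equal(absorbance_at(s, 284), 22.7 * 0.05, tolerance = 1e-12)

  flat <- render_spectrum(c(HMF = 0, LA = 0), cfg0)
  expect_true(all(flat$absorbance == 0))

  # components always sum to the total absorbance
  cfg <- synthetic_config(noise_sd = 0.01, seed = 99)
  s2 <- render_spectrum(c(HMF = 0.05, LA = 30), cfg)
  comp <- spectrum_components(s2)
  expect_equal(rowSums(as.matrix(comp)), s2$absorbance, tolerance = 1e-12)
  expect_true(all(s2$absorbance >= 0))

  # same config (same seed) twice gives identical spectra
  s3 <- render_spectrum(c(HMF = 0.05, LA = 30), cfg)
  expect_identical(s2$absorbance, s3$absorbance)

  expect_error(render_spectrum(c(HMF = 0.05, LA = 0), cfg0, grid = 300),
               "at least 2")
  expect_error(render_spectrum(c(HMF = -1, LA = 0), cfg0), ">= 0")
})

test_that("charcoal model removes the interferent and attenuates analytes by 1/K", {
  cfg <- synthetic_config(noise_sd = 0)
  s <- render_spectrum(c(HMF = 0.05, LA = 30), cfg)

  # dosage 0 is the identity
  expect_equal(charcoal_treat(s, cfg, dosage = 0)$absorbance, s$absorbance)

  # full dosage: interferent gone at 400 nm, analytes scaled by exactly 1/K
  full <- charcoal_treat(s, cfg, dosage = 0.1)
  comp <- spectrum_components(full)
  expect_equal(max(abs(comp$byproduct)), 0)
  comp0 <- spectrum_components(s)
  expect_equal(comp$HMF, comp0$HMF / 69.3, tolerance = 1e-12)
  expect_equal(comp$LA, comp0$LA / 1.62, tolerance = 1e-12)

  # half dosage halves the interferent
  half <- charcoal_treat(s, cfg, dosage = 0.05)
  expect_equal(spectrum_components(half)$byproduct, comp0$byproduct * 0.5,
               tolerance = 1e-12)

  # interferent absorbance at 400 nm strictly decreasing in dosage below 0.1,
  # exactly zero at and above it
  doses <- seq(0, 0.12, by = 0.01)
  a400 <- vapply(doses, function(d) {
    cc <- spectrum_components(charcoal_treat(s, cfg, dosage = d))
    cc$byproduct[s$wavelength_nm == 400]
  }, numeric(1))
  expect_true(all(diff(a400[doses < 0.1]) < 0))
  expect_true(all(a400[doses >= 0.1] == 0))

  expect_error(charcoal_treat(tiny_spectrum(), cfg), "components")
})

test_that("synthetic calibration sets round-trip through the fitter", {
  tab <- make_calibration_set("HMF", slope = 22.7, intercept = 0.006)
  fit <- fit_calibration(tab)
  expect_equal(fit$slope, 22.7, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.006, tolerance = 1e-12)
  expect_equal(tab$concentration, c(0.019, 0.037, 0.056, 0.075, 0.093))

  zero <- make_calibration_set("LA", slope = 1, intercept = 0,
                               concentrations = rep(0, 4))
  expect_true(all(zero$absorbance == 0))

  tab1 <- make_calibration_set("HMF", 22.7, 0.006, noise_sd = 0.01, seed = 42)
  tab2 <- make_calibration_set("HMF", 22.7, 0.006, noise_sd = 0.01, seed = 42)
  expect_identical(tab1, tab2)
  expect_error(make_calibration_set("glucose", 1), "No default standards")
})

test_that("hydrolysate kinetics obey the consecutive first-order closed form", {
  cfg <- synthetic_config()
  g0 <- cfg$kinetics$g0
  ser <- simulate_hydrolysate_series(cfg, times = c(0, 5, 24, 60, 1e5))
  expect_equal(unlist(ser[1, c("glucose", "HMF", "LA")]),
               c(glucose = g0, HMF = 0, LA = 0))
  # asymptotically everything ends up as LA
  expect_equal(unlist(ser[nrow(ser), c("glucose", "HMF", "LA")]),
               c(glucose = 0, HMF = 0, LA = g0), tolerance = 1e-10)
  # conservation at every time, exact by construction
  expect_equal(ser$glucose + ser$HMF + ser$LA, rep(g0, nrow(ser)))

  # HMF maximum at t* = ln(k1/k2)/(k1-k2), against numerical maximisation
  tstar <- hmf_peak_time(cfg)
  expect_equal(tstar, log(0.08 / 0.018) / (0.08 - 0.018))
  hmf_at <- function(t) simulate_hydrolysate_series(cfg, times = t)$HMF
  num <- optimize(hmf_at, c(0, 200), maximum = TRUE)$maximum
  expect_equal(tstar, num, tolerance = 1e-4)

  # k1 == k2 limiting form agrees with the general form nearby
  cfg_eq <- synthetic_config(kinetics = list(k1 = 0.05, k2 = 0.05, g0 = 100))
  cfg_near <- synthetic_config(kinetics = list(k1 = 0.05, k2 = 0.05 + 1e-9, g0 = 100))
  t <- c(1, 10, 50)
  expect_equal(simulate_hydrolysate_series(cfg_eq, t)$HMF,
               simulate_hydrolysate_series(cfg_near, t)$HMF, tolerance = 1e-6)
  expect_equal(hmf_peak_time(cfg_eq), 20)
})

test_that("render -> treat -> quantify recovers the generating contents", {
  cfg <- synthetic_config(noise_sd = 0)
  defs <- method_defaults()
  c_true <- c(HMF = 0.08, LA = 50)
  s <- render_spectrum(c_true, cfg, dilution_factor = 2)
  treated <- charcoal_treat(s, cfg, dosage = 0.1)
  q <- quantify_sample(treated, k = cfg$k)
  # W = C_treated * M * K * R recovers the pre-treatment contents C * M * R
  expected <- unname(c_true * defs$molar_mass[c("HMF", "LA")] * 2)
  expect_equal(q$content, expected, tolerance = 1e-6)
})
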