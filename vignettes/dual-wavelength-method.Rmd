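---
title: "The dual-wavelength UV method for HMF and levulinic acid: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dual-wavelength UV method for HMF and levulinic acid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duowave)
```

## The chemistry and the measurement problem

Hot dilute-acid hydrolysis of glucose produces 5-hydroxymethylfurfural
(HMF), which rehydrates to levulinic acid (LA). Both are UV-active in
water — HMF with its absorption maximum at 284 nm, LA at 266 nm — so a
spectrophotometer can in principle track both during a hydrolysis run.
Two obstacles stand in the way:

1. the HMF and LA bands overlap, so neither wavelength reads a single
   analyte; and
2. side reactions produce colored byproducts absorbing broadly between
   350 and 450 nm, overlapping the analytical region.

The method implemented here resolves (1) by solving the two-component
Beer's-law system at 266 and 284 nm, and (2) by boiling the sample briefly
with activated charcoal, which adsorbs the byproducts completely at a
dosage of 0.1 g per mL of sample. Charcoal also adsorbs part of each
analyte; the correction coefficient
$K = A_\text{before}/A_\text{after}$, measured once per analyte on
standards at its read-out wavelength, compensates for that loss.

## Models

### Calibration and LOQ

`fit_calibration()` fits $A = a + sC$ by ordinary least squares with an
intercept. The slope at 1 cm path length is the molar absorptivity
$\varepsilon$ in mmol$^{-1}$·L·cm$^{-1}$; `molar_absorptivity()` divides by
other path lengths. The limit of quantitation is

$$\mathrm{LOQ} = \frac{a + 10\,|\Delta a|}{s},$$

where $\Delta a$ is the standard error of the intercept. Two readings of
this formula were open:

* **Is the quoted $\pm$ an SE or a confidence half-width?** We take it as
  the standard error, the conventional reading; for the reference lines
  both readings round to the same printed LOQs (0.017 mmol/L for HMF at
  266 nm, 4.68 mmol/L for LA at 284 nm), so nothing downstream depends on
  the choice.
* **Signed or absolute intercept?** The formula is applied with the signed
  intercept exactly as written. For the reference lines $|a|$ would round
  to the same values; the choice is documented rather than silently made.

The reference lines quote $n = 6$ while five standard concentrations are
listed per analyte (possibly a blank made the sixth point); the fitter
accepts any $n \ge 3$ and never assumes a fixed design. Degenerate designs
(all concentrations equal, or fewer than three points) are rejected with
specific errors. A further quirk taken at face value: the reference LOQs
are quoted at each analyte's *non*-maximal wavelength (HMF at 266 nm, LA at
284 nm); `loq()` computes the limit for whatever line it is given, so both
conventions are available.

### Two-component deconvolution

With the byproducts removed, absorbance in the 250–350 nm window is the sum
of the two analytes' contributions, and

$$A_\lambda = l\left(\varepsilon^\lambda_\mathrm{HMF} C_\mathrm{HMF} +
\varepsilon^\lambda_\mathrm{LA} C_\mathrm{LA}\right), \qquad
\lambda \in \{266, 284\}$$

is solved exactly (`solve_two_component()`). The printed source equations
for this system mix up some subscripts (pairing an LA absorptivity with
$C_\mathrm{HMF}$, and back-substituting with a mismatched divisor); the
implementation uses the classical-least-squares form above, the only
reading consistent with Beer's law, and reproduces the intended worked
behaviour (forward-constructed absorbances invert to their generating
concentrations). The 2×2 determinant is checked against
$10^{-12}\max|\varepsilon|^2$ before solving; with the default matrix the
system is well-conditioned (determinant $-0.349$).

Solved concentrations can come out slightly negative when noise pushes a
trace analyte below zero; `quantify_sample()` clamps them to zero and sets
a `negative_clamped` flag rather than erroring, since small negatives near
the LOQ are legitimate measurement outcomes. Contents in the original
hydrolysate follow as $W = C \cdot M \cdot K \cdot R$ in mg/L. Molar
masses default to $M_\mathrm{HMF} = 126.11$ and $M_\mathrm{LA} = 116.12$
g/mol (standard constants, overridable in every entry point).

### Validation statistics

`recovery()` is $100 \times$ measured/added, reported to the nearest
integer percent in tables (full precision kept); `rsd()` uses the sample
($n-1$) standard deviation, a choice the source leaves unstated. Of the
eight reference spiked-recovery records shipped with the package
(`recovery_validation_data()`), six recompute to the reported integer
recovery; HMF records 2 and 3 disagree by about one percentage point
(144/123 = 117.1% vs 116 reported; 173/165 = 104.8% vs 104) and are kept
as reported, flagged, not corrected. The reported LA recovery range
"94–105%" likewise does not cover LA record 3, which recomputes to 108%.

## The synthetic-spectra generator

No instrument data ship with the package; `synthetic_config()` +
`render_spectrum()` provide a forward model in their place.

* **Analyte bands** are Gaussians in wavelength. Each analyte has exactly
  two published absorptivity constraints (its value at 266 and at 284 nm),
  and a two-parameter Gaussian (center fixed at the absorption maximum) is
  the minimal smooth shape through both: $\sigma_\mathrm{HMF} \approx
  16.35$ nm solves $\exp(-18^2/2\sigma^2) = 12.38/22.7$, and
  $\sigma_\mathrm{LA} \approx 18.06$ nm solves the analogous LA ratio
  ($0.014/0.023$). The tests assert both off-peak values are reproduced.
* **The byproduct interferent** is one Gaussian centered at 400 nm with
  $\sigma = 30$ nm, covering the reported 350–450 nm window; its amplitude
  defaults to 0.5 AU — comparable to the analyte signals, so the
  interference is "obvious" — and is configurable.
* **Charcoal treatment** (`charcoal_treat()`) scales the byproduct
  component by $\max(0,\, 1 - d/0.1)$ in dosage $d$ (complete removal at
  0.1 g/mL, the published endpoint) and each analyte component linearly
  from factor 1 at $d = 0$ to $1/K$ at full dosage. Only the endpoints are
  published; the linear interpolation between them is the package's own
  minimal model, and $K$ is treated as a dosage-independent constant as
  published even though a dosage-dependent $K$ would be physically more
  plausible.
* **Noise** is additive Gaussian with configurable SD, truncated so
  absorbance stays non-negative (no noise model is published). All
  randomness flows from the single config seed; per-source components are
  attached to each rendered spectrum so the treatment model can act on
  sources separately, with the components always summing to the total.
* **Kinetics** (`simulate_hydrolysate_series()`) are closed-form
  consecutive first-order reactions glucose → HMF → LA. This is explicitly
  a demonstration driver beyond anything published: the defaults
  $k_1 = 0.08$, $k_2 = 0.018$ min$^{-1}$ put the HMF maximum near 24 min
  (matching the qualitative time-course described for real runs, where HMF
  peaks at 24 min and LA around 29 min) and $g_0 = 333$ mmol/L corresponds
  to 3 g glucose per 50 mL, but no rates were fitted to data and the
  simulated series is never used as an assertion target.

What passing tests on this generator do show: the calibration, correction,
deconvolution and content arithmetic invert the forward model exactly, and
the statistical machinery (slope SEs, RSDs) behaves as OLS theory predicts
under Gaussian noise. What they cannot show: correctness under real
instrument artifacts — baseline drift, stray light, wavelength error,
non-Gaussian noise, byproduct bands of other shapes, or charcoal behaviour
between the published endpoints.

## Numerical choices

* Exact 2×2 solve via LU (`solve()`); no grid search or iteration in the
  production path (a brute-force grid oracle exists only in the tests).
* Linear interpolation for spectrum read-out, no extrapolation outside the
  measured grid — reading single wavelengths off a sampled curve needs no
  stronger assumption.
* CSV dialect fixed (header `wavelength_nm,absorbance`, comma separator,
  decimal point): writing uses shortest round-trip formatting and reading
  uses correctly-rounded base-R parsing, so write → read is bit-identical.
* The JCAMP-DX reader covers single-block `(X++(Y..Y))` files only — the
  common instrument export — rather than the full standard.
* The $k_1 = k_2$ kinetics degeneracy uses the limiting closed form
  $g_0 k_1 t e^{-k_1 t}$; LA is computed by mass balance so conservation
  is exact by construction.
* Test problem sizes, chosen as comfortable desk-scale checks: 1,000
  random concentration pairs for the deconvolution round trip, 20 cases
  against the grid oracle, 200 replicate calibrations for slope/SE
  recovery.

## Known limitations

* $K_\mathrm{HMF} = 69.3$ implies ~98.6% of the HMF is adsorbed by the
  charcoal, leaving very little signal; post-treatment HMF readings in
  realistic mixtures often fall below the 0.017 mmol/L LOQ (the README
  example shows exactly this flag). The constant is used as published.
* The published repeatability RSDs (4.47% for HMF, 2.25% for LA) cannot be
  recomputed — the replicate instrument readings behind them are not
  available — and the published reaction time-course reports masses in
  grams without a stated conversion to mg/L. Both are covered only by
  synthetic surrogates in the test suite and are never asserted against.
* Uncertainty is not propagated through the 2×2 solve; only calibration
  uncertainties are reported.
* No baseline correction, smoothing or scatter correction: the method as
  specified operates on raw absorbances.
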