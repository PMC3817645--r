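# duowave

Dual-wavelength UV spectrophotometric quantification of
5-hydroxymethylfurfural (HMF) and levulinic acid (LA) in acid glucose
hydrolysate.

When glucose is hydrolyzed in hot dilute sulfuric acid it dehydrates to HMF,
which rehydrates to LA — the platform chemicals biorefinery work cares about.
Both absorb in the UV (HMF peaks at 284 nm, LA at 266 nm), so a plain
spectrophotometer can replace HPLC/GC for process monitoring — provided two
complications are handled: the two bands overlap, and the hydrolysate carries
colored byproducts absorbing at 350–450 nm. `duowave` implements the
computational side of that method for chemists and process engineers:
calibration, interference correction, the two-component deconvolution, content
computation, and recovery/RSD validation, plus a synthetic-spectra generator
so everything can be exercised without an instrument.

## The method

**Calibration.** For each analyte, absorbance follows Beer's law
*A* = *a* + *s·C* (OLS with intercept); at 1 cm path length the slope *s* is
the molar absorptivity ε (mmol⁻¹·L·cm⁻¹). The limit of quantitation is

LOQ = (*a* + 10·|Δ*a*|) / *s*,

with Δ*a* the standard error of the intercept. The reference lines give
ε<sub>HMF</sub> = 12.38 / 22.7 and ε<sub>LA</sub> = 0.023 / 0.014 at
266 / 284 nm, and LOQ = 0.017 mmol/L (HMF) and 4.68 mmol/L (LA).

**Charcoal correction.** Boiling the sample with activated charcoal
(0.1 g/mL) removes the byproduct interference completely, but also adsorbs
part of each analyte. The correction coefficient
*K* = *A*<sub>before</sub>/*A*<sub>after</sub> at the analyte's read-out
wavelength (284 nm for HMF, 266 nm for LA) compensates: *K*<sub>HMF</sub> = 69.3,
*K*<sub>LA</sub> = 1.62.

**Dual-wavelength deconvolution.** The treated spectrum is read at both
wavelengths and the 2×2 Beer's-law system

*A*<sub>λ</sub> = *l* · (ε<sub>HMF</sub><sup>λ</sup>·*C*<sub>HMF</sub> + ε<sub>LA</sub><sup>λ</sup>·*C*<sub>LA</sub>),  λ ∈ {266, 284}

is solved exactly for the two concentrations. Contents in the original
hydrolysate follow as *W* = *C* · *M* · *K* · *R* (mg/L), with *M* the molar
mass and *R* the dilution factor.

**Validation.** Spiked recovery (100 × measured/added) and relative standard
deviation (100 × sd/mean) summarize accuracy and repeatability.

## Worked example

```r
library(duowave)

# fit a calibration line from (synthetic) standards
cal <- make_calibration_set("HMF", slope = 22.7, intercept = 0.006,
                            noise_sd = 0.01, seed = 7)
fit_calibration(cal, analyte = "HMF", wavelength = 284)
#> <uv_calibration> HMF @ 284 nm
#>   A = 0.02112(+/-0.01336) + 22.39(+/-0.2159) C   (n = 5, r^2 = 0.9997)
#>   LOQ = 0.00691 mmol/L

# simulate a hydrolysate spectrum (C_HMF = 0.05, C_LA = 30 mmol/L, with the
# byproduct interferent), treat it with charcoal, quantify
cfg     <- synthetic_config(noise_sd = 0)
s       <- render_spectrum(c(HMF = 0.05, LA = 30), cfg)
treated <- charcoal_treat(s, cfg, dosage = 0.1)
run_pipeline(treated)
#> == dual-wavelength UV quantification ==
#> wavelengths_nm: 266, 284
#> path_length_cm: 1
#> dilution_R: 1
#> absorbance: A266=0.434858 A284=0.275637
#> epsilon[HMF]: 12.38, 22.7 (at 266, 284 nm)
#> epsilon[LA]: 0.023, 0.014 (at 266, 284 nm)
#> constants[HMF]: K=69.3 M=126.11 g/mol LOQ=0.017 mmol/L
#> constants[LA]: K=1.62 M=116.12 g/mol LOQ=4.68 mmol/L
#> result[HMF]: C=0.00072150072 mmol/L W=6.3055 mg/L flags=below_loq
#> result[LA]: C=18.518519 mmol/L W=3483.6 mg/L flags=ok
```

Reading the output: the charcoal-treated solution contains 18.5 mmol/L LA;
scaled by *M* = 116.12 g/mol and *K* = 1.62 this recovers the generating
30 mmol/L × 116.12 = 3483.6 mg/L in the untreated hydrolysate. The HMF
read-out (0.0007 mmol/L after 69.3-fold adsorption loss) sits below the
0.017 mmol/L LOQ and is flagged accordingly — with K_HMF = 69.3 very little
HMF signal survives treatment, a documented caveat of the method.

The validation statistics on the reference spiked-recovery records:

```r
summary(recovery_table(recovery_validation_data()))
#> # A tibble: 2 × 4
#>   analyte     n min_recovery max_recovery
#>   <chr>   <int>        <dbl>        <dbl>
#> 1 HMF         4           88          117
#> 2 LA          4           94          108
```

A thin command-line interface wraps the same functions
(`exec/duowave calibrate | quantify | validate | simulate`); see
`inst/extdata/method_config.yaml` for the run-configuration format.

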