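Package: duowave
Title: Dual-Wavelength UV Quantification of 5-Hydroxymethylfurfural and
    Levulinic Acid in Glucose Hydrolysate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the simultaneous spectrophotometric determination of
    5-hydroxymethylfurfural (HMF) and levulinic acid (LA) in acid glucose
    hydrolysate by a dual-wavelength (266/284 nm) UV method. Fits Beer's-law
    calibration lines and limits of quantitation, corrects for activated-charcoal
    adsorption of analytes and colored byproducts, solves the two-component
    Beer's-law system for mixture concentrations, converts them to hydrolysate
    contents, and computes spiked-recovery and relative-standard-deviation
    validation statistics. A synthetic-spectra generator (Gaussian absorption
    bands, byproduct interferent, charcoal treatment model, consecutive
    first-order hydrolysis kinetics) stands in for the instrument so the whole
    workflow is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    utils,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
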