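Package: dualdia
Title: Dual-Window DIA Scheme Design and Isotope-Dilution Absolute
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs data-independent acquisition (DIA) isolation-window
    schemes that place light/heavy stable-isotope peptide pairs into
    adjacent narrow windows while tiling the remaining m/z range with
    variable-width wide windows for global proteome profiling. Includes
    peptide mass and b/y fragment-ion arithmetic with C-terminal
    (13C/15N) isotope labels, multi-protease in-silico digestion and
    variant-peptide panel selection, the complete stable-isotope-dilution
    absolute-quantification workflow (light-to-heavy ratios, linear
    calibration with LOD/LOQ, relative error and CV, mutant-versus-
    wild-type metrics), spectrum and chromatogram utilities (cosine
    similarity, XIC areas, signal-to-noise, pathway z-scores,
    differential-expression filtering), and a seeded DIA acquisition
    simulator so the entire workflow can be exercised and tested without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
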