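Package: hepavisc
Title: Liver Viscoelasticity from Shear-Wave and Oscillatory-Shear Dispersion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of liver shear elasticity and viscosity from
    shear-wave dispersion (160-380 Hz), dynamic mechanical analysis
    (1-41 Hz) and a combined wide-band Kelvin-Voigt fit. Includes a planar
    shear-wave field simulator in attenuating viscoelastic media, the full
    ultrafast-ultrasound post-processing chain (autocorrelation velocity
    estimation, despeckling, temporal interpolation, directional filtering,
    per-frequency phase regression), a synthetic five-stage steatosis rat
    cohort generator with tunable cross-method correlation, and the study's
    statistical analysis (outlier exclusion, ANOVA with Tukey-Kramer,
    Pearson correlation, ROC staging with Youden cutoffs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
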