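# hepavisc

Liver tissue behaves like a Kelvin–Voigt solid under shear: a spring
(elasticity μ, Pa) in parallel with a dashpot (viscosity η, Pa·s), with
complex modulus G\*(ω) = μ + iωη. Because a shear wave in such a medium is
dispersive,

c_s(ω) = sqrt( 2(μ² + ω²η²) / ( ρ (μ + sqrt(μ² + ω²η²)) ) ),

measuring phase velocity across frequency and inverting this relation
yields (μ, η). This package implements that estimation for the two
instruments used in small-animal steatosis studies — shear wave
elastography (SWE, 160–380 Hz, in vivo) and dynamic mechanical analysis
(DMA, 1–41 Hz, ex vivo) — plus the combined 1–380 Hz Voigt analysis, and
everything needed to run the whole study synthetically:

* a planar shear-wave movie simulator with exact Voigt dispersion and
  attenuation (complex wavenumber k\* = ω·sqrt(ρ/G\*)), IQ modulation, noise
  and boundary reflections;
* the full SWE post-processing chain: lag-one autocorrelation velocity
  estimation, 3×3 median + axial averaging, 5× spline interpolation,
  reverberation-frame removal, zero-phase 1 kHz low-pass, f-k directional
  filtering, per-frequency Fourier phase regression, Voigt inversion;
* the DMA chain: stiffness/phase sweeps → geometry-corrected storage and
  loss moduli → dispersion → Voigt fit;
* a 69-rat five-stage steatosis cohort generator (stage-specific bivariate
  parameters, Gaussian copula with tunable SWE↔DMA correlation, replicate
  noise);
* the study statistics: 1.5·IQR outlier exclusion, Welch t tests, one-way
  ANOVA with Tukey–Kramer comparisons, Pearson correlation, nonparametric
  ROC with Youden cutoffs and Hanley–McNeil intervals.

It is intended for elastography methodologists who want a tested,
end-to-end reference implementation of dispersion-based viscoelasticity
estimation and of the statistical pipeline around it.

## Worked example

Simulate a healthy-stage liver acquisition and estimate its parameters:

```r
library(hepavisc)

truth <- rheo_params("voigt", mu = 860, eta = 0.77)  # Pa, Pa.s
movie <- simulate_planar_wave(truth, seed = 1)
fit   <- swe_estimate(movie)
print(fit)
#> <fit_result> voigt: mu = 827.5 Pa, eta = 0.7669 Pa.s | R2 = 0.9973, RSS = 0.000966, n = 12
```

The pipeline measured 12 phase-velocity points across 160–380 Hz and the
Voigt inversion recovered elasticity within ~4% and viscosity within ~0.5%
of the simulated truth — elasticity is the weakly identified parameter in
this band, where the loss term ωη dominates the modulus.

Run the full synthetic study (cohort → per-rat fits → statistics):

```r
rep <- run_study(seed = 1, mode = "fast")
print(rep)
#> <study_report>
#>   69 rats, stages: 17/14/19/12/7
#>   elasticity SWE~DMA: r = 0.630 (p = 6.59e-09)
#>   viscosity  SWE~DMA: r = 0.090 (p = 0.463)
#>   ROC S0 vs S1-S4: AUROC 0.641, cutoff 1.52 kPa
#>   ROC S0-S1 vs S2-S4: AUROC 0.694, cutoff 1.52 kPa
```

The cohort generator is calibrated so that per-rat SWE and DMA elasticity
correlate at 0.628 while the viscosities are uncorrelated; the report
summarizes stage means after outlier exclusion, the stage-wise ANOVA and
Tukey–Kramer pairs, and ROC staging on the combined-band elasticity.

The numbered scripts under `analysis/` run the same components as a
narrative workflow (`01_swe_pipeline.R`, `02_dma_analysis.R`,
`03_model_comparison.R`, `04_cohort_study.R`), writing their tables under
`results/`.

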