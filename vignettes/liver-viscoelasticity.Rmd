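---
title: "Estimating liver viscoelasticity from shear-wave and oscillatory-shear dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating liver viscoelasticity from shear-wave and oscillatory-shear dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepavisc)
```

## The model

Soft tissue responds to shear like a spring and a dashpot in parallel: the
Kelvin--Voigt model with complex shear modulus

$$G^*(\omega) = \mu + i\,\omega\eta,$$

where $\mu$ (Pa) is the shear elasticity and $\eta$ (Pa s) the shear
viscosity. A plane shear wave in such a medium is dispersive; its phase
velocity is

$$c_s(\omega) \;=\; \sqrt{\frac{2(\mu^2+\omega^2\eta^2)}
  {\rho\,(\mu+\sqrt{\mu^2+\omega^2\eta^2})}},$$

equivalently, for any linear viscoelastic medium with storage and loss
moduli $(G', G'')$,

$$c(\omega) \;=\; \sqrt{\frac{2(G'^2+G''^2)}
  {\rho\,(G'+\sqrt{G'^2+G''^2})}}.$$

The two forms are algebraically identical when $G'=\mu$, $G''=\omega\eta$;
the test suite verifies the identity to $10^{-12}$ relative over $10^4$
random parameter draws. Fitting measured $c(f)$ curves with this relation
by nonlinear least squares yields $(\hat\mu, \hat\eta)$.

Two instruments observe different windows of this dispersion relation:

* **SWE** (shear wave elastography): an ultrafast ultrasound acquisition
  tracks a propagating shear wave; phase velocities are measured at
  160--380 Hz.
* **DMA** (dynamic mechanical analysis): oscillatory shear on an excised
  specimen measures $(G', G'')$ directly at 1--41 Hz.

A third, *combined* analysis merges both curves and fits a single Voigt
model over 1--380 Hz.

Maxwell ($G^* = i\omega\eta\mu/(\mu+i\omega\eta)$) and Zener (a spring
$\mu$ in parallel with a Maxwell arm $\mu_2$--$\eta$) models are provided
for comparison. These are the standard series and standard-linear-solid
forms; where only the model names are conventionally given, these
parameterizations are our explicit choice, documented here.

## Density

Tissue mass density is never measured in this kind of study; we use the
soft-tissue convention $\rho = 1000\ \mathrm{kg/m^3}$ everywhere, exposed
as an argument in every function that needs it.

## The wavefield simulator

`simulate_planar_wave()` synthesizes particle-velocity movies of a planar
shear wavefront entering the lateral edge of the imaging region. The push
physics that creates a quasi-planar wavefront in vivo (sequenced focused
acoustic-radiation-force pushes) is deliberately not modeled; the wave
enters at the $x=0$ column and the field is uniform with depth.

Each spectral component propagates with the medium's complex wavenumber
$k^*(f) = \omega\sqrt{\rho/G^*}$, so dispersion and attenuation are exact
by construction. The source has a Gaussian amplitude spectrum, center
270 Hz and spectral $\sigma$ 220 Hz by default, covering the 160--380 Hz
analysis band; the pulse is injected with its center 2 ms into the record.
That timing places the packet's transit through the near-source columns
inside the 5 ms observation window (50 frames at a PRF of 10 kHz), which
is what makes the Fourier phases of those columns trustworthy; it is the
single most important default in the simulator. Amplitude is normalized so
the source column peaks at 1 cm/s, a typical tracked particle velocity.
Measurement noise is white Gaussian on the velocity samples with an
explicit seed (the 5%-of-peak convention is provided by
`default_noise_sd()`); a single mirrored wave from the far lateral
boundary models a reflection when requested.

`velocity_to_iq()` phase-modulates a complex baseband carrier with the
integrated displacement, the signal model that the lag-one autocorrelation
estimator (`iq_to_particle_velocity()`) inverts; with a 1-pixel kernel the
round trip is exact to machine precision, and the default 3x3 kernel
trades a small lateral blur for noise robustness.

### What the simulator does not emulate

No speckle statistics, no beamforming or tracking jitter beyond additive
white noise, no depth-dependent wavefront curvature, no multiple
reflections, no physiological motion. Passing pipeline tests on these
movies therefore demonstrates correctness of the *processing*, not
robustness to every artifact of an in vivo acquisition.

## The SWE processing chain

`swe_estimate()` composes the stages in acquisition order:

1. lag-one autocorrelation of the IQ data (when present), averaged over a
   3x3 spatial kernel;
2. 3x3 median filter per frame plus a 10-pixel axial boxcar (reflect
   padding; the grid is unchanged);
3. five-fold cubic-spline temporal interpolation
   (Forsythe--Malcolm--Moler end conditions: linear ramps are reproduced
   exactly, and an in-band sinusoid is reproduced to better than $10^{-4}$
   of its amplitude);
4. removal of the leading reverberation frames (default 2; the count is
   not a physical constant and is configurable) and a zero-phase low-pass
   at 1000 Hz, implemented as a fourth-order Butterworth magnitude response
   applied in the frequency domain so that no phase distortion enters the
   dispersion estimate;
5. a directional filter over (lateral, time), see below;
6. per-frequency phase regression: the temporal Fourier transform is
   evaluated *at each analysis frequency directly* (a Goertzel-style
   matrix product), the phase is unwrapped along the lateral direction
   with standard $2\pi$ jump correction and regressed on position;
   $c(f) = -2\pi f/(d\phi/dx)$, with the spread of per-depth slopes as the
   per-point uncertainty;
7. a bounded Voigt least-squares fit of the resulting curve.

Evaluating the transform at the exact analysis frequencies deserves a
note: a 5 ms record gives a DFT bin spacing of roughly 200 Hz, so
nearest-bin readout on a power-of-two grid cannot resolve a 20 Hz
frequency step. For a transient that is fully contained in the window the
discrete transform at *any* frequency equals the continuous Fourier
transform, so direct evaluation is both exact and cheap; containment is
what the lateral gate enforces.

### Lateral gating

Only part of the lateral extent carries usable phase information: columns
the wave has not yet fully traversed within the record (or where
attenuation has buried it) would bias the regression. `lateral_gate()`
selects columns whose depth-averaged envelope (i) reaches at least 2% of
the strongest column, and (ii) is quiet at both ends of the record (mean
envelope below 10% of the column peak over the leading 8% of frames and
below 15% over the trailing 8%), i.e. the packet both entered and exited
there. The first two columns are excluded outright as the wave-injection
zone, and the gate is restricted to the contiguous run containing the
strongest usable column. The gate is computed *before* the Fourier-domain
filters, whose circular wrap-around would otherwise smear the envelope
edges. Frequencies whose total unwrapped phase span across the gate is
below $\pi/4$, or whose fitted slope is non-negative, are dropped as
unreliable; fewer than three surviving frequencies is an error.

### The directional filter and strongly lossy media

The directional filter zeroes the two quadrants of the 2D (lateral
wavenumber, frequency) spectrum that carry waves traveling toward the
source (with the negative-exponent FFT convention in both axes, a
+x-traveling wave occupies the quadrants where
$\mathrm{sign}(k_x) = -\mathrm{sign}(\omega)$). On direction-pure periodic
fields the mask is exact: identity for forward waves, complete rejection
of mirrored ones.

Liver at these parameters is, however, *extremely* lossy in the SWE band:
for $\mu = 0.86$ kPa, $\eta = 0.77$ Pa s the loss tangent at 270 Hz is
about 1.5 and the attenuation length ($\approx 1.5$ mm) is shorter than a
wavelength ($\approx 5$ mm). The lateral decay of a purely forward wave
then spreads genuine forward energy across the $k_x = 0$ line, and
unconditional quadrant zeroing measurably distorts the retained field --
enough to corrupt the phase regression of a field that contains no
reflection at all. The filter is therefore *energy-adaptive*: it first
measures the backward-quadrant energy fraction and acts only when that
fraction exceeds a threshold (default 0.25). A forward-only transient in a
lossy medium sits near 0.13 and passes untouched; an interfering
reflection of comparable amplitude pushes the fraction well above the
threshold and is suppressed. The measured fraction is recorded on the
movie for inspection. This adaptivity is a design choice of this package:
it preserves the filter's purpose (rescuing measurements that reflections
would otherwise destroy) without taxing clean acquisitions with the
distortion the mask necessarily inflicts in high-loss media.

## The DMA module

The instrument record is a stiffness ratio $|F^*/X^*|$ (N/m) and phase lag
$\delta$ per frequency on the 9-point grid 1, 6, ..., 41 Hz. Conversion to
moduli divides by the specimen shape factor
$SF = \mathrm{width}\times\mathrm{length}/\mathrm{thickness}$ (default
5 x 15 / 4 mm $= 0.01875$ m):

$$G' = \frac{|F^*/X^*|\cos\delta}{SF}, \qquad
  G'' = \frac{|F^*/X^*|\sin\delta}{SF}.$$

The loss modulus takes $\sin\delta$ -- the imaginary part of
$(\sigma_0/\varepsilon_0)(\cos\delta + i\sin\delta)$ -- so that
$G'^2+G''^2 = (|F^*/X^*|/SF)^2$ holds identically (asserted in the tests)
and $\tan\delta = G''/G'$ is geometry-invariant. Strain amplitude (1%) and
bath temperature (38.1 deg C) are carried as metadata only. Since
instruments report either $(G', G'')$ directly or the raw
stiffness-and-phase record, both entry points exist (`modulus_sweep()` and
`dma_raw_sweep()`).

## The synthetic cohort

`generate_cohort()` draws a five-stage steatosis cohort of 69 rats
(17/14/19/12/7 in S0--S4) with, per rat, latent true $(\mu,\eta)$ pairs
for each method from stage-specific Gaussians. The per-stage means and SDs
(see `default_stage_specs()`) are the study conditions this package
emulates -- e.g. S0: SWE 0.86 kPa / 0.77 Pa s, DMA 1.12 kPa / 5.40 Pa s.
The joint SWE--DMA sampling model is not something a summary table
determines; our explicit modeling choice is a Gaussian copula over the
four parameters in which SWE and DMA elasticity correlate at 0.628 (the
cross-method agreement the generator is calibrated to), the viscosities at
0 (the two bands measure essentially unrelated viscosities), and all other
cross-pairs are independent. A calibration test (200 cohorts) checks that
the realized cohort-level Pearson correlation lands within 0.1 of the
target. Draws are clamped from below at 10% of the stage mean to keep
parameters positive; the clamping is rare and mild, so the copula
correlation survives essentially intact.

Replicates (10 SWE, 3 DMA per rat) multiply the truth by
$(1 + N(0, 0.10))$; the 10% within-rat coefficient of variation is chosen
so per-rat standard errors resemble the stage-level spreads. Fat fraction
is uniform within the stage's histologic interval (0--4, 5--25, 26--50,
51--75, above 75 percent; the unassigned (75, 76) sliver maps to S4 so
staging is total). `cohort_to_curves()` provides a fast analytic mode
(dispersion curves evaluated from measurement-level parameters) and a
full-physics mode that pushes every replicate through the wavefield
simulator and the SWE pipeline, and through the synthetic DMA instrument.

## Fitting: numerical choices

`fit_dispersion()` minimizes the (optionally inverse-variance weighted)
squared velocity residuals with bounded L-BFGS-B, $\mu \in (0, 100]$ kPa,
$\eta \in [0, 100]$ Pa s, from a deterministic 3x3 multi-start grid over
decades ($\mu_0 \in \{0.1, 1, 10\}$ kPa $\times$
$\eta_0 \in \{0.1, 1, 10\}$ Pa s; the Zener second spring starts at
$\mu_{2,0} = \mu_0$), followed by a tight polish from the winner; residual
ties break toward the smaller viscosity. $R^2 = 1 - RSS/TSS$ is reported
as `NA` when the data are constant (zero TSS), rather than dividing by
zero. All public interfaces take frequencies in Hz; the $\omega = 2\pi f$
conversion happens once, inside the model evaluation. Default fits are
*unweighted*, matching the convention of fitting stage-mean curves;
inverse-variance weighting is available.

Two identifiability facts shape interpretation. In the SWE band the loss
term $\omega\eta$ dominates $\mu$, so elasticity is weakly identified
there: percent-level curve errors move $\hat\mu$ by several percent while
$\hat\eta$ barely moves. Conversely the combined 1--380 Hz fit of two
*conflicting* band truths is not an interpolation: the high band's shallow
slope forces a small $\hat\eta$, and $\hat\mu$ must then rise *above*
both band-wise elasticities to meet the low-band velocities. Fitting the
stage-mean parameter curves gives combined elasticities of roughly
1.4--1.7 kPa against band-wise values of 0.86--1.39 kPa; the per-band
residual split is reported (`band_rss`) so the tension is visible.

## Statistics

The analysis chain mirrors standard practice for this design: per-rat
means; 1.5 IQR fences within each stage group (type-7 quantiles -- the
convention matters because exclusion sets depend on it); Welch t tests
between methods per stage; one-way ANOVA with Tukey--Kramer pairwise
comparisons across stages (critical values from the studentized-range
distribution; an independent numerical-integration oracle checks
$q_{0.05,3,10} \approx 3.88$); Pearson correlation with the exact t
transform; and nonparametric ROC with the rank/Mann--Whitney AUROC
estimator (half credit for ties, verified against brute-force pair
counting), Youden-optimal cutoffs (ties toward the lower cutoff), and
Hanley--McNeil 95% confidence intervals clipped to [0, 1]. The CI method
is our choice; published AUROC intervals for comparable data are not
generally reproducible without knowing the original method, and no test
asserts them.

## Problem sizes

The default acquisition is 100 x 150 pixels x 50 frames; a full SWE
simulate-and-estimate cycle takes a few seconds. Monte-Carlo checks use
50 seeds for fit recovery, 50 cohorts for ordering properties and 200
cohorts for copula calibration; the full-physics cross-check runs one
two-replicate rat. These sizes keep the whole suite at a few minutes
while leaving the statistical assertions comfortably powered.

## Known limitations

* The directional filter inevitably distorts phase in media whose
  attenuation length approaches the wavelength; the adaptive threshold
  avoids the unnecessary cases but a genuinely reflected wave in such a
  medium is suppressed at a few-percent velocity-bias cost.
* SWE-band elasticity is weakly identified (above); single-movie
  $\hat\mu$ errors of several percent are expected even noiselessly.
* The cohort generator reproduces first and second moments and one
  cross-method correlation, not the full joint distribution of real
  animals; ROC and Tukey outcomes on synthetic cohorts vary from seed to
  seed accordingly.
* No fractional-derivative or power-law rheology; no frequency-dependent
  density; no 2D elasticity maps (single-ROI scalar outputs).
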