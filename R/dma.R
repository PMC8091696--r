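#' DMA specimen geometry
#'
#' Parallel-plate shear specimen dimensions. The default 5 x 15 x 4 mm block
#' matches the liver-slab preparation the oscillatory shear protocol uses.
#'
#' @param width,length,thickness Dimensions in m.
#' @return A `specimen_geometry` list.
#' @export
specimen_geometry <- function(width = 0.005, length = 0.015,
                              thickness = 0.004) {
  stopifnot(width > 0, length > 0, thickness > 0)
  structure(list(width = width, length = length, thickness = thickness),
            class = "specimen_geometry")
}

#' Shape factor of a shear specimen
#'
#' The geometric factor converting the measured stiffness ratio (N/m) to a
#' modulus (Pa): cross-sectional area over thickness,
#' `width * length / thickness` (units m).
#'
#' @param geometry A [specimen_geometry].
#' @return Shape factor, m.
#' @export
#' @examples
#' shape_factor(specimen_geometry()) # 0.01875 m
shape_factor <- function(geometry = specimen_geometry()) {
  stopifnot(inherits(geometry, "specimen_geometry"))
  geometry$width * geometry$length / geometry$thickness
}

#' Raw DMA frequency sweep
#'
#' Instrument-level record of an oscillatory shear sweep: per frequency, the
#' complex stiffness magnitude \eqn{|F^*/X^*|} (N/m) and the stress--strain
#' phase lag \eqn{\delta} (rad), plus the specimen geometry. Strain
#' amplitude and bath temperature are carried as metadata only; they affect
#' the instrument, not the conversion to moduli.
#'
#' @param freqs Frequencies, Hz (strictly increasing; default the 9-point
#'   1--41 Hz grid at 5 Hz spacing).
#' @param stiffness_ratio |F*/X*| per frequency, N/m (> 0).
#' @param delta Phase lag per frequency, rad, in `[0, pi/2)`.
#' @param geometry A [specimen_geometry].
#' @param strain_amplitude Relative strain (metadata; default 0.01).
#' @param temperature_c Bath temperature, deg C (metadata; default 38.1).
#' @return A `dma_raw_sweep` object.
#' @export
dma_raw_sweep <- function(freqs = dma_default_freqs(), stiffness_ratio, delta,
                          geometry = specimen_geometry(),
                          strain_amplitude = 0.01, temperature_c = 38.1) {
  stopifnot(length(freqs) == length(stiffness_ratio),
            length(freqs) == length(delta),
            all(diff(freqs) > 0), all(stiffness_ratio > 0))
  if (any(delta < 0 | delta >= pi / 2))
    stop("phase lag delta must lie in [0, pi/2)")
  structure(list(freqs = as.numeric(freqs),
                 stiffness_ratio = as.numeric(stiffness_ratio),
                 delta = as.numeric(delta), geometry = geometry,
                 strain_amplitude = strain_amplitude,
                 temperature_c = temperature_c),
            class = "dma_raw_sweep")
}

#' Default DMA frequency grid
#'
#' 1 to 41 Hz at 5 Hz intervals: 1, 6, 11, ..., 41 Hz (9 points).
#'
#' @return Numeric vector of frequencies, Hz.
#' @export
dma_default_freqs <- function() seq(1, 41, by = 5)

#' Storage and loss moduli from a raw DMA sweep
#'
#' Geometry-corrected conversion of the stiffness-and-phase record to the
#' complex shear modulus:
#' \deqn{G' = \frac{|F^*/X^*| \cos\delta}{SF}, \qquad
#'       G'' = \frac{|F^*/X^*| \sin\delta}{SF},}
#' with SF the [shape_factor]. (The loss modulus takes \eqn{\sin\delta}, the
#' imaginary part of \eqn{(\sigma_0/\varepsilon_0) e^{i\delta}};
#' \eqn{G'^2 + G''^2 = (|F^*/X^*|/SF)^2} always.)
#'
#' @param sweep A [dma_raw_sweep].
#' @return A [modulus_sweep].
#' @export
moduli_from_raw <- function(sweep) {
  stopifnot(inherits(sweep, "dma_raw_sweep"))
  sf <- shape_factor(sweep$geometry)
  modulus_sweep(sweep$freqs,
                g_storage = sweep$stiffness_ratio * cos(sweep$delta) / sf,
                g_loss = sweep$stiffness_ratio * sin(sweep$delta) / sf)
}

#' Dispersion curve from DMA moduli
#'
#' Pointwise conversion of (G', G'') to shear-wave phase velocity via
#' [phase_velocity_from_modulus], tagged as the DMA band.
#'
#' @param moduli A [modulus_sweep].
#' @param rho Mass density, kg/m^3.
#' @return A [dispersion_curve] with band `"dma"`.
#' @export
dma_dispersion <- function(moduli, rho = 1000) {
  stopifnot(inherits(moduli, "modulus_sweep"))
  dispersion_curve(moduli$freq_hz,
                   phase_velocity_from_modulus(moduli$g_storage_pa,
                                               moduli$g_loss_pa, rho),
                   band = "dma")
}

#' Simulate a raw DMA sweep from a rheological model
#'
#' Synthetic oscillatory-shear instrument: evaluates the model's
#' \eqn{G^*(\omega)} on the sweep grid and inverts the geometry correction to
#' stiffness ratio and phase lag, with multiplicative Gaussian noise on the
#' stiffness ratio and additive Gaussian noise on the phase.
#'
#' @param params True medium [rheo_params].
#' @param geometry A [specimen_geometry].
#' @param freqs Sweep grid, Hz.
#' @param noise_rel Relative noise level: SD of the multiplicative stiffness
#'   noise; `0.2 * noise_rel` rad is used as the SD of the additive phase
#'   noise.
#' @param seed Integer seed.
#' @return A [dma_raw_sweep].
#' @export
simulate_dma_sweep <- function(params, geometry = specimen_geometry(),
                               freqs = dma_default_freqs(), noise_rel = 0,
                               seed = 1L) {
  stopifnot(inherits(params, "rheo_params"), noise_rel >= 0)
  g <- complex_modulus(params, freqs)
  sf <- shape_factor(geometry)
  mag <- sqrt(g$g_storage^2 + g$g_loss^2)
  stiff <- mag * sf
  delta <- atan2(g$g_loss, g$g_storage)
  if (noise_rel > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    stiff <- stiff * (1 + stats::rnorm(length(stiff), sd = noise_rel))
    delta <- delta + stats::rnorm(length(delta), sd = 0.2 * noise_rel)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    stiff <- pmax(stiff, 1e-6)
    delta <- pmin(pmax(delta, 0), pi / 2 - 1e-9)
  }
  dma_raw_sweep(freqs, stiff, delta, geometry)
}

#' End-to-end DMA viscoelasticity estimate
#'
#' Raw sweep to moduli to dispersion to Voigt fit on the 1--41 Hz band.
#'
#' @param sweep A [dma_raw_sweep].
#' @param rho Mass density, kg/m^3.
#' @return A `fit_result` with the DMA [dispersion_curve] attached as
#'   `$curve`.
#' @export
dma_estimate <- function(sweep, rho = 1000) {
  curve <- dma_dispersion(moduli_from_raw(sweep), rho)
  fit <- fit_dispersion(curve, "voigt", rho = rho)
  fit$curve <- curve
  fit
}

#' Write / read a raw DMA sweep as CSV (+ JSON geometry sidecar)
#'
#' Columns: `freq_hz, stiffness_n_per_m, delta_rad`. The geometry is written
#' to `<path>.geom.json`.
#'
#' @param sweep A [dma_raw_sweep].
#' @param path CSV file path.
#' @return `read_dma_csv` returns a [dma_raw_sweep]; `write_dma_csv` returns
#'   `path` invisibly.
#' @export
write_dma_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "dma_raw_sweep"))
  utils::write.csv(data.frame(freq_hz = sweep$freqs,
                              stiffness_n_per_m = sweep$stiffness_ratio,
                              delta_rad = sweep$delta),
                   path, row.names = FALSE)
  jsonlite::write_json(sweep$geometry[c("width", "length", "thickness")],
                       paste0(path, ".geom.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dma_csv
#' @export
read_dma_csv <- function(path) {
  df <- utils::read.csv(path)
  gpath <- paste0(path, ".geom.json")
  geom <- if (file.exists(gpath)) {
    gj <- jsonlite::read_json(gpath)
    specimen_geometry(gj$width, gj$length, gj$thickness)
  } else specimen_geometry()
  dma_raw_sweep(df$freq_hz, df$stiffness_n_per_m, df$delta_rad, geom)
}
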