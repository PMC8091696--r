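#' Ultrafast plane-wave acquisition configuration
#'
#' Geometry and timing of the synthetic shear-wave acquisition: a
#' (depth x lateral x time) grid tracked at the detection pulse repetition
#' frequency. Defaults mirror a typical small-animal liver protocol:
#' 50 detect pulses at a PRF of 10 kHz with a 6.25 MHz carrier, over a
#' 5 mm (axial) x 15 mm (lateral) region of interest.
#'
#' @param prf Pulse repetition frequency, Hz.
#' @param n_frames Number of tracked frames (>= 2).
#' @param roi_axial,roi_lateral Region-of-interest extent, m.
#' @param pitch_axial,pitch_lateral Pixel pitch, m.
#' @param carrier_freq Detection center frequency, Hz.
#' @param sound_speed Compressional sound speed used for IQ demodulation, m/s.
#' @return An `acq_config` list with derived grid sizes `n_z`, `n_x` and
#'   coordinate vectors `z`, `x`, `t`.
#' @export
acq_config <- function(prf = 10000, n_frames = 50, roi_axial = 0.005,
                       roi_lateral = 0.015, pitch_axial = 5e-5,
                       pitch_lateral = 1e-4, carrier_freq = 6.25e6,
                       sound_speed = 1540) {
  stopifnot(prf > 0, n_frames >= 2, roi_axial > 0, roi_lateral > 0,
            pitch_axial > 0, pitch_lateral > 0, carrier_freq > 0,
            sound_speed > 0)
  n_z <- max(2L, round(roi_axial / pitch_axial))
  n_x <- max(2L, round(roi_lateral / pitch_lateral))
  structure(list(prf = prf, n_frames = as.integer(n_frames),
                 roi_axial = roi_axial, roi_lateral = roi_lateral,
                 pitch_axial = pitch_axial, pitch_lateral = pitch_lateral,
                 carrier_freq = carrier_freq, sound_speed = sound_speed,
                 n_z = n_z, n_x = n_x,
                 z = (seq_len(n_z) - 1) * pitch_axial,
                 x = (seq_len(n_x) - 1) * pitch_lateral,
                 t = (seq_len(n_frames) - 1) / prf),
            class = "acq_config")
}

new_wavefield_movie <- function(v, config, iq = NULL, truth = NULL,
                                rho = NULL) {
  stopifnot(is.array(v), length(dim(v)) == 3L, all(is.finite(v)))
  structure(list(v = v, iq = iq, config = config, truth = truth, rho = rho),
            class = "wavefield_movie")
}

#' @export
print.wavefield_movie <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("<wavefield_movie> %d z x %d x x %d frames @ %g kHz%s%s\n",
              d[1], d[2], d[3], x$config$prf / 1000,
              if (!is.null(x$iq)) ", IQ present" else "",
              if (!is.null(x$truth))
                sprintf(" | truth %s mu=%.3g eta=%.3g", x$truth$model,
                        x$truth$mu, x$truth$eta) else ""))
  invisible(x)
}

#' Simulate a planar shear-wave particle-velocity movie
#'
#' Synthesizes plane shear-wave propagation along +x in a homogeneous
#' viscoelastic medium. A broadband pulse with Gaussian amplitude spectrum
#' enters at the x = 0 column and propagates per the medium's complex
#' wavenumber \eqn{k^*(f) = \omega\sqrt{\rho/G^*}}: each spectral component
#' travels at its own phase velocity and decays as
#' \eqn{\exp(-\alpha(f)\,x)}. The field is uniform with depth (planar front;
#' the focused-push physics that creates the quasi-planar wave in vivo is
#' deliberately not modeled). An optional boundary echo is added as a single
#' mirrored wave re-entering from the far lateral edge, and white Gaussian
#' measurement noise is drawn from an explicit seed.
#'
#' @param params True medium [rheo_params] (recorded in the movie for
#'   round-trip validation).
#' @param rho Mass density, kg/m^3.
#' @param config An [acq_config].
#' @param source_spectrum List with `center_freq` (Hz), `bandwidth` (Hz;
#'   Gaussian spectral-amplitude sigma), and optionally `t0` (pulse center
#'   time at x = 0, s; default 2 ms, placing the packet's transit through the
#'   near-source columns inside the 5 ms observation window) and `amplitude`
#'   (peak particle velocity at the source column, m/s; default 0.01).
#' @param noise_sd Additive Gaussian noise SD, m/s (absolute; see
#'   [default_noise_sd] for the 5%-of-peak convention).
#' @param reflect_coeff Amplitude reflection coefficient of the far lateral
#'   boundary, in `[0, 1]`.
#' @param seed Integer seed for the noise draw.
#' @return A `wavefield_movie` with the velocity field `v` (m/s) on the
#'   (n_z, n_x, n_frames) grid, the generating truth, and `rho`.
#' @export
simulate_planar_wave <- function(params, rho = 1000, config = acq_config(),
                                 source_spectrum = list(center_freq = 270,
                                                        bandwidth = 220),
                                 noise_sd = 0, reflect_coeff = 0,
                                 seed = 1L) {
  stopifnot(inherits(params, "rheo_params"), inherits(config, "acq_config"),
            reflect_coeff >= 0, reflect_coeff <= 1, noise_sd >= 0)
  f0 <- source_spectrum$center_freq
  bw <- source_spectrum$bandwidth
  t0 <- source_spectrum$t0 %||% 2e-3
  amp <- source_spectrum$amplitude %||% 0.01
  nyq <- config$prf / 2
  if (f0 + 2.5 * bw >= nyq)
    stop("source band reaches the detection Nyquist frequency")
  if (f0 <= 0 || bw <= 0) stop("source center_freq and bandwidth must be > 0")

  # spectral synthesis on a fine frequency grid spanning the Gaussian band
  df <- 2
  freqs <- seq(max(df, f0 - 4 * bw), min(nyq - df, f0 + 4 * bw), by = df)
  a <- amp * exp(-(freqs - f0)^2 / (2 * bw^2))
  kw <- complex_wavenumber(params, rho, freqs)

  x <- config$x
  tt <- config$t
  n_x <- config$n_x
  n_t <- config$n_frames
  # phase matrices: (n_f x n_x) spatial, (n_f x n_t) temporal
  # v(x,t) = Re sum_f a_f exp(-alpha x) exp(i(2 pi f (t - t0) - k x))
  vslice <- matrix(0, n_x, n_t)
  decay <- exp(-outer(kw$alpha, x))            # n_f x n_x
  phx <- outer(kw$k_re, x)                     # n_f x n_x
  pht <- 2 * pi * outer(freqs, tt - t0)        # n_f x n_t
  # accumulate Re{ e^{i pht} * e^{-i phx} } = cos(pht - phx)
  cf <- (a * decay) * cos(phx); sf <- (a * decay) * sin(phx)
  vslice <- t(cf) %*% cos(pht) + t(sf) %*% sin(pht)
  # normalize so the source column peaks at `amplitude` m/s
  vslice <- vslice * (amp / max(abs(vslice[1, ])))
  if (reflect_coeff > 0) {
    xr <- 2 * max(x) - x                       # path via the far boundary
    decr <- exp(-outer(kw$alpha, xr))
    phxr <- outer(kw$k_re, xr)
    cfr <- (reflect_coeff * a * decr) * cos(phxr)
    sfr <- (reflect_coeff * a * decr) * sin(phxr)
    vslice <- vslice + t(cfr) %*% cos(pht) + t(sfr) %*% sin(pht)
  }
  v <- aperm(array(rep(vslice, each = config$n_z),
                   dim = c(config$n_z, n_x, n_t)), c(1, 2, 3))
  if (noise_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    v <- v + array(stats::rnorm(length(v), sd = noise_sd), dim = dim(v))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  new_wavefield_movie(v, config, truth = params, rho = rho)
}

#' Default measurement-noise level for a movie
#'
#' The acquisition-noise convention used throughout: an SD equal to 5% of the
#' peak absolute particle velocity of the corresponding noiseless field.
#'
#' @param movie A noiseless `wavefield_movie`.
#' @param frac Fraction of peak |v| (default 0.05).
#' @return Noise SD in m/s.
#' @export
default_noise_sd <- function(movie, frac = 0.05) {
  frac * max(abs(movie$v))
}

#' Modulate a velocity movie onto synthetic IQ data
#'
#' Integrates particle velocity to displacement and phase-modulates a complex
#' baseband carrier: \eqn{IQ = A_0 \exp(i\,4\pi f_c d / c)}, the signal model
#' that a lag-one autocorrelation velocity estimator inverts. Lets the IQ
#' stage of the processing pipeline be exercised end to end.
#'
#' @param movie A `wavefield_movie` with `v` present.
#' @param a0 Carrier amplitude (arbitrary units).
#' @return The movie with `iq` populated.
#' @export
velocity_to_iq <- function(movie, a0 = 1) {
  stopifnot(inherits(movie, "wavefield_movie"), !is.null(movie$v))
  cfg <- movie$config
  dt <- 1 / cfg$prf
  d <- aperm(apply(movie$v, c(1, 2), cumsum), c(2, 3, 1)) * dt
  phase <- 4 * pi * cfg$carrier_freq * d / cfg$sound_speed
  movie$iq <- a0 * exp(1i * phase)
  movie
}

`%||%` <- function(a, b) if (is.null(a)) b else a
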