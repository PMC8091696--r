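#' SWE post-processing pipeline configuration
#'
#' Parameters of the five-stage shear-wave post-processing chain:
#' autocorrelation velocity estimation, despeckling (3x3 median + 10-pixel
#' axial averaging), five-fold cubic-spline temporal interpolation,
#' reverberation-frame removal and 1 kHz zero-phase low-pass, directional
#' filtering, and per-frequency phase regression over 160--380 Hz.
#'
#' @param median_kernel Side of the square median filter, pixels (odd).
#' @param axial_avg Axial boxcar length, pixels.
#' @param interp_factor Temporal interpolation factor (>= 1).
#' @param lpf_cutoff Low-pass cutoff, Hz.
#' @param reverb_frames_dropped Leading frames removed before filtering.
#' @param band Analysis band `c(lo, hi)`, Hz.
#' @param freq_step Spacing of analysis frequencies in the band, Hz.
#' @param gate_frac Lateral columns whose peak |v| falls below this fraction
#'   of the strongest column are excluded from phase regression (the wave has
#'   not reached them, or attenuation has buried them).
#' @param head_tol,tail_tol A column is used only if its mean |v| over the
#'   first (`head_tol`) and last (`tail_tol`) `edge_frac` of frames is below
#'   this multiple of its peak, i.e. the wave packet both entered and exited
#'   the observation window there.
#' @param edge_frac Fraction of frames inspected at each end for containment.
#' @param exclude_push_cols Leading lateral columns excluded outright: the
#'   wave-injection zone (the push region in a real acquisition) is not
#'   usable for tracking.
#' @param min_phase_span Frequencies whose total unwrapped phase span across
#'   the gated columns is below this (rad) are dropped as unreliable.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(median_kernel = 3, axial_avg = 10,
                            interp_factor = 5, lpf_cutoff = 1000,
                            reverb_frames_dropped = 2,
                            band = c(160, 380), freq_step = 20,
                            gate_frac = 0.02, head_tol = 0.10,
                            tail_tol = 0.15, edge_frac = 0.08,
                            exclude_push_cols = 2,
                            min_phase_span = pi / 4) {
  stopifnot(median_kernel %% 2 == 1, median_kernel >= 1, axial_avg >= 1,
            interp_factor >= 1, lpf_cutoff > 0, reverb_frames_dropped >= 0,
            length(band) == 2, band[1] > 0, band[2] > band[1],
            band[2] < lpf_cutoff, freq_step > 0, exclude_push_cols >= 0)
  structure(list(median_kernel = as.integer(median_kernel),
                 axial_avg = as.integer(axial_avg),
                 interp_factor = as.integer(interp_factor),
                 lpf_cutoff = lpf_cutoff,
                 reverb_frames_dropped = as.integer(reverb_frames_dropped),
                 band = band, freq_step = freq_step,
                 gate_frac = gate_frac, head_tol = head_tol,
                 tail_tol = tail_tol, edge_frac = edge_frac,
                 exclude_push_cols = as.integer(exclude_push_cols),
                 min_phase_span = min_phase_span),
            class = "pipeline_config")
}

# reflect-padded index
.pad_idx <- function(n, k) {
  i <- seq_len(n + 2 * k) - k
  i[i < 1] <- 2 - i[i < 1]
  i[i > n] <- 2 * n - i[i > n]
  i
}

# vectorized 3x3 median over (z, x) for every frame, via a comparator network
.median3x3 <- function(v) {
  d <- dim(v)
  iz <- .pad_idx(d[1], 1L)
  ix <- .pad_idx(d[2], 1L)
  vp <- v[iz, ix, , drop = FALSE]
  n9 <- vector("list", 9L)
  k <- 1L
  for (dz in 0:2) for (dx in 0:2) {
    n9[[k]] <- vp[dz + seq_len(d[1]), dx + seq_len(d[2]), , drop = FALSE]
    k <- k + 1L
  }
  swap <- function(i, j) {
    lo <- pmin(n9[[i]], n9[[j]]); hi <- pmax(n9[[i]], n9[[j]])
    n9[[i]] <<- lo; n9[[j]] <<- hi
  }
  # 19-comparator median-of-9 network (Paeth)
  swap(1,2); swap(4,5); swap(7,8); swap(2,3); swap(5,6); swap(8,9)
  swap(1,2); swap(4,5); swap(7,8); swap(1,4); swap(4,7); swap(2,5)
  swap(5,8); swap(3,6); swap(6,9); swap(3,5); swap(5,7); swap(3,5)
  n9[[5]]
}

#' Despeckle a velocity movie
#'
#' Per frame: square median filter over (depth, lateral), then a boxcar mean
#' along depth. Edges are reflect-padded; the grid is unchanged.
#'
#' @param movie A `wavefield_movie` with `v`.
#' @param config A [pipeline_config].
#' @return The filtered movie.
#' @export
despeckle <- function(movie, config = pipeline_config()) {
  stopifnot(inherits(movie, "wavefield_movie"), !is.null(movie$v))
  d <- dim(movie$v)
  if (d[1] < config$median_kernel || d[2] < config$median_kernel ||
      d[1] < config$axial_avg)
    stop("grid smaller than despeckle kernels")
  v <- if (config$median_kernel == 3) .median3x3(movie$v) else movie$v
  # axial boxcar via cumulative sums on the reflect-padded array
  k <- config$axial_avg
  if (k > 1) {
    half_lo <- (k - 1L) %/% 2L
    half_hi <- k - 1L - half_lo
    iz <- .pad_idx(d[1], max(half_lo, half_hi))
    pad <- max(half_lo, half_hi)
    vp <- v[iz, , , drop = FALSE]
    cs <- apply(vp, c(2, 3), cumsum)           # (n_z+2p, n_x, n_t)
    top <- cs[pad + seq_len(d[1]) + half_hi, , , drop = FALSE]
    ilo <- pad + seq_len(d[1]) - half_lo - 1L
    bot <- array(0, dim(top))
    pos <- ilo >= 1L
    bot[pos, , ] <- cs[ilo[pos], , , drop = FALSE]
    v <- (top - bot) / k
  }
  movie$v <- v
  movie
}

#' Temporal cubic-spline interpolation
#'
#' Resamples the slow-time axis by an integer factor using cubic splines
#' (Forsythe--Malcolm--Moler end conditions, so low-order polynomial signals
#' are reproduced exactly); original samples are preserved.
#'
#' @param movie A `wavefield_movie`.
#' @param factor Integer interpolation factor (default 5).
#' @return Movie with `n_t -> factor * (n_t - 1) + 1` frames and the config's
#'   `prf` scaled accordingly.
#' @export
temporal_interpolate <- function(movie, factor = 5L) {
  stopifnot(inherits(movie, "wavefield_movie"), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(movie)
  d <- dim(movie$v)
  n_new <- factor * (d[3] - 1L) + 1L
  m <- matrix(aperm(movie$v, c(3, 1, 2)), nrow = d[3])
  xout <- seq(1, d[3], length.out = n_new)
  mi <- apply(m, 2, function(y) stats::spline(seq_len(d[3]), y,
                                              xout = xout)$y)
  movie$v <- aperm(array(mi, dim = c(n_new, d[1], d[2])), c(2, 3, 1))
  cfg <- movie$config
  cfg$prf <- cfg$prf * factor
  cfg$n_frames <- n_new
  cfg$t <- cfg$t[1] + (seq_len(n_new) - 1) / cfg$prf
  movie$config <- cfg
  movie
}

#' Reverberation removal and zero-phase low-pass filtering
#'
#' Drops the leading reverberation-contaminated frames, then applies a
#' zero-phase low-pass along slow time (fourth-order Butterworth magnitude
#' response applied in the frequency domain, so no phase distortion enters
#' the dispersion estimate).
#'
#' @param movie A `wavefield_movie`.
#' @param config A [pipeline_config].
#' @return The band-conditioned movie.
#' @export
band_condition <- function(movie, config = pipeline_config()) {
  stopifnot(inherits(movie, "wavefield_movie"))
  drop <- config$reverb_frames_dropped
  d <- dim(movie$v)
  if (drop >= d[3] - 2) stop("cannot drop almost all frames")
  if (drop > 0) {
    movie$v <- movie$v[, , (drop + 1):d[3], drop = FALSE]
    cfg <- movie$config
    cfg$n_frames <- dim(movie$v)[3]
    cfg$t <- cfg$t[(drop + 1):length(cfg$t)]
    movie$config <- cfg
    d <- dim(movie$v)
  }
  fs <- movie$config$prf
  if (config$lpf_cutoff >= fs / 2) return(movie)   # nothing to remove
  n_t <- d[3]
  f <- (seq_len(n_t) - 1) / n_t * fs
  f <- pmin(f, fs - f)
  h <- 1 / (1 + (f / config$lpf_cutoff)^8)         # |H|^2 of 4th-order Butterworth
  m <- matrix(aperm(movie$v, c(3, 1, 2)), nrow = n_t)
  m <- Re(stats::mvfft(stats::mvfft(m) * h, inverse = TRUE)) / n_t
  movie$v <- aperm(array(m, dim = c(n_t, d[1], d[2])), c(2, 3, 1))
  movie
}

#' Directional filter (reflection suppression)
#'
#' Two-dimensional Fourier filtering over (lateral, time) at each depth:
#' spectral quadrants carrying waves that travel toward -x are zeroed, and
#' the real part of the inverse transform is returned. With the forward FFT
#' convention used here (negative-exponent transform in both axes), a
#' +x-traveling wave \eqn{\cos(\omega t - kx)} maps to the quadrants where
#' \eqn{\mathrm{sign}(k_x) = -\mathrm{sign}(\omega)}; those are kept
#' (together with the \eqn{k_x = 0} and \eqn{\omega = 0} lines).
#'
#' The filter is energy-adaptive: in a strongly attenuating medium a purely
#' forward-traveling transient spreads real energy across the sign of
#' \eqn{k_x} (its lateral decay length is comparable to a wavelength), so
#' unconditional quadrant zeroing would distort a field that contains no
#' reflection at all. The backward-quadrant energy fraction is therefore
#' measured first; below `threshold` the field is returned unchanged.
#'
#' @param movie A `wavefield_movie`.
#' @param threshold Backward-quadrant energy fraction below which the filter
#'   is a no-op (default 0.25).
#' @return Movie containing (predominantly) the +x-traveling field, with
#'   attribute-like field `backward_fraction` recording the measured value.
#' @export
directional_filter <- function(movie, threshold = 0.25) {
  stopifnot(inherits(movie, "wavefield_movie"), !is.null(movie$v))
  d <- dim(movie$v)
  n_x <- d[2]; n_t <- d[3]
  kx_sign <- ifelse(seq_len(n_x) - 1 == 0, 0,
                    ifelse(seq_len(n_x) - 1 <= (n_x - 1) %/% 2, 1, -1))
  w_sign <- ifelse(seq_len(n_t) - 1 == 0, 0,
                   ifelse(seq_len(n_t) - 1 <= (n_t - 1) %/% 2, 1, -1))
  sgn <- outer(kx_sign, w_sign)
  mask <- (sgn <= 0) * 1
  e_fwd <- 0; e_bwd <- 0
  ft_all <- vector("list", d[1])
  for (z in seq_len(d[1])) {
    ft <- stats::fft(movie$v[z, , ])
    ft_all[[z]] <- ft
    pw <- Mod(ft)^2
    e_fwd <- e_fwd + sum(pw[sgn < 0])
    e_bwd <- e_bwd + sum(pw[sgn > 0])
  }
  bf <- e_bwd / (e_fwd + e_bwd)
  movie$backward_fraction <- bf
  if (bf >= threshold) {
    for (z in seq_len(d[1]))
      movie$v[z, , ] <- Re(stats::fft(ft_all[[z]] * mask,
                                      inverse = TRUE)) / (n_x * n_t)
  }
  movie
}

#' Particle velocity from IQ data (lag-one autocorrelation)
#'
#' Kasai-style estimator: the phase of the lag-one slow-time autocorrelation
#' of the complex baseband signal, averaged over a small 2D spatial kernel,
#' scaled to velocity by \eqn{c \cdot \mathrm{PRF} / (4\pi f_c)}. Exact for
#' sub-wavelength inter-frame displacements.
#'
#' @param movie A `wavefield_movie` with `iq` populated.
#' @param kernel Side of the spatial averaging kernel (odd; default 3).
#' @return Movie with `v` replaced by the estimate (first frame duplicated
#'   so the grid is unchanged).
#' @export
iq_to_particle_velocity <- function(movie, kernel = 3L) {
  stopifnot(inherits(movie, "wavefield_movie"))
  if (is.null(movie$iq)) stop("movie has no IQ data")
  cfg <- movie$config
  d <- dim(movie$iq)
  ac <- movie$iq[, , 2:d[3], drop = FALSE] *
    Conj(movie$iq[, , 1:(d[3] - 1), drop = FALSE])
  if (kernel > 1) {
    k <- as.integer(kernel) %/% 2L
    iz <- .pad_idx(d[1], k); ix <- .pad_idx(d[2], k)
    acp <- ac[iz, ix, , drop = FALSE]
    acc <- array(0 + 0i, dim = dim(ac))
    for (dz in 0:(2 * k)) for (dx in 0:(2 * k))
      acc <- acc + acp[dz + seq_len(d[1]), dx + seq_len(d[2]), , drop = FALSE]
    ac <- acc
  }
  vhat <- Arg(ac) * cfg$sound_speed * cfg$prf / (4 * pi * cfg$carrier_freq)
  movie$v <- array(0, dim = d)
  movie$v[, , 2:d[3]] <- vhat
  movie$v[, , 1] <- vhat[, , 1]
  movie$iq <- NULL
  movie
}

#' Lateral column gating for phase regression
#'
#' Selects the lateral positions where the phase of the temporal Fourier
#' transform is trustworthy: the depth-averaged envelope must reach at least
#' `gate_frac` of the strongest column (the wave actually got there above the
#' attenuation floor), and the wave packet must be fully contained in the
#' observation window (mean envelope over the first and last `tail_frac` of
#' frames below `tail_tol` of the column peak). Computed before the Fourier-
#' domain filters, whose circular wrap-around would otherwise smear the
#' envelope edges.
#'
#' @param movie A `wavefield_movie`.
#' @param config A [pipeline_config].
#' @return Logical vector over lateral columns.
#' @export
lateral_gate <- function(movie, config = pipeline_config()) {
  d <- dim(movie$v)
  s <- apply(abs(movie$v), c(2, 3), mean)       # n_x x n_t
  peak <- apply(s, 1, max)
  n_edge <- max(1L, round(config$edge_frac * d[3]))
  head_m <- rowMeans(s[, seq_len(n_edge), drop = FALSE])
  tail_m <- rowMeans(s[, d[3] - seq_len(n_edge) + 1L, drop = FALSE])
  use <- peak >= config$gate_frac * max(peak) &
    head_m <= config$head_tol * peak & tail_m <= config$tail_tol * peak
  if (config$exclude_push_cols > 0)
    use[seq_len(min(config$exclude_push_cols, d[2]))] <- FALSE
  # keep the contiguous run containing the strongest usable column
  if (any(use)) {
    r <- rle(use)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    jmax <- which(use)[which.max(peak[use])]
    k <- which(r$values & starts <= jmax & ends >= jmax)
    use <- rep(FALSE, d[2])
    use[starts[k]:ends[k]] <- TRUE
  }
  use
}

# unwrap a phase vector (2*pi jump correction)
.unwrap <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' Per-frequency phase-velocity spectrum
#'
#' At each analysis frequency the temporal Fourier transform is evaluated at
#' every pixel; the phase is unwrapped along the lateral direction, and a
#' least-squares regression of phase on lateral position gives the local
#' wavenumber, hence \eqn{c(f) = -2\pi f / (d\phi/dx)}. Per-depth slopes
#' provide the point spread. Lateral columns are first gated on energy and
#' wave-packet containment (see [pipeline_config]); frequencies with
#' non-negative slope or insufficient phase span are dropped.
#'
#' @param movie A despeckled, band-conditioned, directionally filtered
#'   `wavefield_movie`.
#' @param config A [pipeline_config].
#' @return A [dispersion_curve] (band `"swe"`) with attribute `n_dropped`,
#'   the number of analysis frequencies discarded.
#' @export
phase_velocity_spectrum <- function(movie, config = pipeline_config()) {
  stopifnot(inherits(movie, "wavefield_movie"), !is.null(movie$v))
  cfg <- movie$config
  d <- dim(movie$v)
  freqs <- seq(config$band[1], config$band[2], by = config$freq_step)
  if (max(freqs) >= cfg$prf / 2) stop("analysis band exceeds Nyquist")

  use <- movie$gate %||% lateral_gate(movie, config)
  if (sum(use) < 5) stop("fewer than 5 usable lateral positions after gating")
  xs <- cfg$x[use]

  tt <- cfg$t - cfg$t[1]
  ew <- exp(-2i * pi * outer(tt, freqs))        # n_t x n_f
  m <- matrix(aperm(movie$v, c(3, 1, 2)), nrow = d[3])  # t x (z*x)
  spec <- crossprod(ew, m)                      # n_f x (z*x)
  spec <- array(spec, dim = c(length(freqs), d[1], d[2]))

  xs_c <- xs - mean(xs)
  sxx <- sum(xs_c^2)
  c_est <- c_sd <- rep(NA_real_, length(freqs))
  for (i in seq_along(freqs)) {
    ph <- Arg(spec[i, , use, drop = FALSE])     # 1 x n_z x n_use
    slopes <- apply(ph[1, , , drop = TRUE], 1, function(p) {
      pu <- .unwrap(p)
      sum(xs_c * (pu - mean(pu))) / sxx
    })
    # mean-phase slope across depths for the point estimate
    pu_mean <- .unwrap(Arg(colSums(spec[i, , use, drop = FALSE][1, , ,
                                                                drop = TRUE])))
    span <- abs(pu_mean[length(pu_mean)] - pu_mean[1])
    slope <- sum(xs_c * (pu_mean - mean(pu_mean))) / sxx
    if (slope >= 0 || span < config$min_phase_span) next
    c_est[i] <- -2 * pi * freqs[i] / slope
    cz <- -2 * pi * freqs[i] / slopes[slopes < 0]
    c_sd[i] <- if (length(cz) > 1) stats::sd(cz) else 0
  }
  ok <- is.finite(c_est) & c_est > 0
  if (sum(ok) < 3) stop("fewer than 3 valid frequencies in the band")
  out <- dispersion_curve(freqs[ok], c_est[ok], c_sd[ok], band = "swe")
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' End-to-end SWE viscoelasticity estimate
#'
#' Runs the full post-processing chain on a movie (starting from IQ data if
#' present, otherwise from particle velocity) and fits the Voigt dispersion
#' relation to the resulting phase-velocity curve.
#'
#' @param movie A `wavefield_movie`.
#' @param config A [pipeline_config].
#' @param rho Mass density, kg/m^3; defaults to the movie's `rho` or 1000.
#' @return A `fit_result` (Voigt) with the measured [dispersion_curve]
#'   attached as `$curve`.
#' @export
swe_estimate <- function(movie, config = pipeline_config(), rho = NULL) {
  rho <- rho %||% movie$rho %||% 1000
  if (!is.null(movie$iq)) movie <- iq_to_particle_velocity(movie)
  movie <- despeckle(movie, config)
  movie <- temporal_interpolate(movie, config$interp_factor)
  movie$gate <- lateral_gate(movie, config)
  movie <- band_condition(movie, config)
  movie <- directional_filter(movie)
  curve <- phase_velocity_spectrum(movie, config)
  fit <- fit_dispersion(curve, "voigt", rho = rho)
  fit$curve <- curve
  fit
}
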