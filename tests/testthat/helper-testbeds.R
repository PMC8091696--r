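# Shared constructions and independent oracles used across test files.

# Steady-state plane-wave movie with tones exactly on the record's DFT grid
# (f multiples of prf / n_frames), so Fourier-domain operations are exact.
# sign = +1 builds a +x-traveling wave, -1 the mirrored (-x) wave.
steady_wave_movie <- function(freqs, amps, c0, config = acq_config(),
                              sign = +1, rho = 1000) {
  stopifnot(length(freqs) == length(amps))
  v <- array(0, dim = c(config$n_z, config$n_x, config$n_frames))
  for (j in seq_along(freqs)) {
    k <- 2 * pi * freqs[j] / c0
    ph <- outer(-sign * k * config$x, 2 * pi * freqs[j] * config$t, "+")
    v <- v + amps[j] * aperm(array(rep(cos(ph), each = config$n_z),
                                   c(config$n_z, config$n_x,
                                     config$n_frames)), c(1, 2, 3))
  }
  structure(list(v = v, iq = NULL, config = config, truth = NULL, rho = rho),
            class = "wavefield_movie")
}

# Brute-force AUROC: explicit pair counting with half credit for ties.
auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Studentized-range CDF by direct numerical integration (independent of
# stats::ptukey): P(Q <= q) for k means and nu df, via the classical
# double integral over the range of k standard normals and the chi
# distribution of the pooled SD.
srange_cdf_numint <- function(q, k, nu) {
  inner <- function(s) {
    f_range <- function(u) {
      k * stats::dnorm(u) * (stats::pnorm(u) - stats::pnorm(u - q * s))^(k - 1)
    }
    stats::integrate(f_range, -8, 8, rel.tol = 1e-9)$value
  }
  dens_s <- function(s) {
    # density of S/sigma with nu df: chi_nu / sqrt(nu)
    exp((nu / 2) * log(nu) - lgamma(nu / 2) - (nu / 2 - 1) * log(2) +
          (nu - 1) * log(s) - nu * s^2 / 2)
  }
  stats::integrate(function(s) vapply(s, function(si) dens_s(si) * inner(si),
                                      numeric(1)),
                   0, 8, rel.tol = 1e-7)$value
}

# Invert the numerical CDF for the critical value.
srange_q_numint <- function(p, k, nu) {
  stats::uniroot(function(q) srange_cdf_numint(q, k, nu) - p,
                 c(0.5, 20), tol = 1e-6)$root
}

# Voigt phase velocity through an independent route: c = omega / Re(k*),
# with k* = omega * sqrt(rho / G*) evaluated by complex arithmetic.
voigt_c_wavenumber_oracle <- function(mu, eta, rho, freq) {
  w <- 2 * pi * freq
  gstar <- complex(real = mu, imaginary = w * eta)
  k <- w * sqrt(rho / gstar)
  w / Re(k)
}
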