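#' Rheological model parameters
#'
#' Bundle a rheological model identity with its constitutive constants.
#' Three classical spring--dashpot networks are supported:
#' \describe{
#'   \item{voigt}{spring \eqn{\mu} and dashpot \eqn{\eta} in parallel;
#'     \eqn{G^*(\omega) = \mu + i\omega\eta}. The standard model for liver
#'     shear-wave dispersion.}
#'   \item{maxwell}{spring and dashpot in series;
#'     \eqn{G^*(\omega) = i\omega\eta\mu / (\mu + i\omega\eta)}; fluid-like
#'     at low frequency.}
#'   \item{zener}{standard linear solid: spring \eqn{\mu} in parallel with a
#'     Maxwell arm (\eqn{\mu_2}, \eqn{\eta});
#'     \eqn{G^*(\omega) = \mu + i\omega\eta\mu_2 / (\mu_2 + i\omega\eta)}.}
#' }
#'
#' @param model One of `"voigt"`, `"maxwell"`, `"zener"`.
#' @param mu Shear elasticity, Pa (> 0).
#' @param eta Shear viscosity, Pa s (>= 0).
#' @param mu2 Second spring constant, Pa; required for (and only for) the
#'   Zener model.
#' @return An object of class `rheo_params`.
#' @export
#' @examples
#' rheo_params("voigt", mu = 860, eta = 0.77)
rheo_params <- function(model = c("voigt", "maxwell", "zener"), mu, eta,
                        mu2 = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu), mu > 0,
            is.numeric(eta), length(eta) == 1L, is.finite(eta), eta >= 0)
  if (model == "zener") {
    if (is.null(mu2) || !is.finite(mu2) || mu2 <= 0)
      stop("zener model requires mu2 > 0")
  } else {
    if (!is.null(mu2)) stop("mu2 is only meaningful for the zener model")
    mu2 <- NULL
  }
  structure(list(model = model, mu = mu, eta = eta, mu2 = mu2),
            class = "rheo_params")
}

#' @export
print.rheo_params <- function(x, ...) {
  cat(sprintf("<rheo_params> %s: mu = %.4g Pa, eta = %.4g Pa.s", x$model,
              x$mu, x$eta))
  if (!is.null(x$mu2)) cat(sprintf(", mu2 = %.4g Pa", x$mu2))
  cat("\n")
  invisible(x)
}

#' Complex shear modulus of a rheological model
#'
#' Evaluate \eqn{G^*(\omega) = G' + iG''} at given frequencies.
#'
#' @param params A [rheo_params] object.
#' @param freq Frequency in Hz (>= 0), vectorized.
#' @return A list with numeric vectors `g_storage` (G', Pa) and
#'   `g_loss` (G'', Pa).
#' @export
complex_modulus <- function(params, freq) {
  stopifnot(inherits(params, "rheo_params"), all(freq >= 0))
  w <- 2 * pi * freq
  g <- switch(params$model,
    voigt   = complex(real = rep(params$mu, length(w)),
                      imaginary = w * params$eta),
    maxwell = {
      gi <- 1i * w * params$eta * params$mu / (params$mu + 1i * w * params$eta)
      gi[w == 0] <- 0 + 0i
      gi
    },
    zener   = params$mu +
      1i * w * params$eta * params$mu2 / (params$mu2 + 1i * w * params$eta),
    stop("unknown model: ", params$model)
  )
  list(g_storage = Re(g), g_loss = Im(g))
}

#' Shear-wave phase velocity from the complex modulus
#'
#' For a linear viscoelastic medium the phase velocity of a plane shear wave
#' is
#' \deqn{c = \sqrt{ \frac{2 (G'^2 + G''^2)}{\rho\,(G' + \sqrt{G'^2 + G''^2})} }.}
#'
#' @param g_storage Storage modulus G', Pa (> 0), vectorized.
#' @param g_loss Loss modulus G'', Pa (>= 0).
#' @param rho Mass density, kg/m^3 (default 1000, soft-tissue convention).
#' @return Phase velocity, m/s.
#' @export
phase_velocity_from_modulus <- function(g_storage, g_loss, rho = 1000) {
  stopifnot(rho > 0, all(g_loss >= 0))
  if (any(g_storage <= 0))
    stop("phase velocity is undefined for non-positive storage modulus")
  mag <- sqrt(g_storage^2 + g_loss^2)
  sqrt(2 * (g_storage^2 + g_loss^2) / (rho * (g_storage + mag)))
}

#' Voigt-model phase velocity (dispersion relation)
#'
#' \deqn{c_s(\omega) = \sqrt{ \frac{2(\mu^2 + \omega^2\eta^2)}
#'   {\rho (\mu + \sqrt{\mu^2 + \omega^2\eta^2})} }, \quad \omega = 2\pi f.}
#'
#' @param mu Shear elasticity, Pa.
#' @param eta Shear viscosity, Pa s.
#' @param rho Mass density, kg/m^3.
#' @param freq Frequency, Hz (> 0), vectorized.
#' @return Phase velocity, m/s.
#' @export
#' @examples
#' voigt_phase_velocity(mu = 860, eta = 0.77, freq = 270) # ~1.42 m/s
voigt_phase_velocity <- function(mu, eta, rho = 1000, freq) {
  stopifnot(rho > 0, all(freq > 0))
  if (mu <= 0 && eta <= 0) stop("mu and eta cannot both be zero")
  w <- 2 * pi * freq
  mag <- sqrt(mu^2 + w^2 * eta^2)
  sqrt(2 * (mu^2 + w^2 * eta^2) / (rho * (mu + mag)))
}

#' Complex wavenumber in a viscoelastic medium
#'
#' Generalizes \eqn{c = \sqrt{|G^*|/\rho}} to the complex wavenumber
#' \eqn{k^* = \omega \sqrt{\rho / G^*}}; the real part gives the phase
#' (\eqn{c = \omega / \mathrm{Re}\,k^*}) and the negative imaginary part the
#' attenuation coefficient in Np/m.
#'
#' @inheritParams complex_modulus
#' @param rho Mass density, kg/m^3.
#' @return A list with numeric vectors `k_re` (rad/m) and `alpha` (Np/m).
#' @export
complex_wavenumber <- function(params, rho = 1000, freq) {
  stopifnot(all(freq > 0), rho > 0)
  g <- complex_modulus(params, freq)
  gstar <- complex(real = g$g_storage, imaginary = g$g_loss)
  if (any(Mod(gstar) == 0)) stop("complex modulus is zero; wavenumber undefined")
  k <- 2 * pi * freq * sqrt(rho / gstar)
  list(k_re = Re(k), alpha = -Im(k))
}
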