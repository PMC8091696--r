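#' Fit a rheological model to a dispersion curve
#'
#' Nonlinear least squares on phase velocity versus frequency: minimizes
#' \eqn{\sum_i w_i (c_i - c_{\mathrm{model}}(f_i))^2} over the model
#' parameters, with box bounds \eqn{\mu \in (0, 100\,\mathrm{kPa}]},
#' \eqn{\eta \in [0, 100\,\mathrm{Pa\,s}]} (and the same bounds as \eqn{\mu}
#' for the Zener \eqn{\mu_2}). Optimization is bounded quasi-Newton
#' (`L-BFGS-B`) from a deterministic 3x3 multi-start grid spanning decades of
#' (\eqn{\mu}, \eqn{\eta}); the best residual sum of squares wins, ties going
#' to the smaller fitted viscosity.
#'
#' @param curve A [dispersion_curve] with at least 3 points (4 for zener).
#' @param model `"voigt"`, `"maxwell"` or `"zener"`.
#' @param rho Mass density, kg/m^3.
#' @param weights `"none"` (default; fits mean curves unweighted) or
#'   `"inverse_variance"` (weights 1/sd^2 from the curve's `c_sd_mps`).
#' @return A `fit_result` list: `params` ([rheo_params]), `r2`, `rss`
#'   ((m/s)^2), `converged`, `n_points`. `r2` is `NA` when the data have zero
#'   total sum of squares.
#' @export
#' @examples
#' cv <- model_dispersion(rheo_params("voigt", 1390, 6.27),
#'                        freqs = seq(1, 41, by = 5), band = "dma")
#' fit_dispersion(cv, "voigt")
fit_dispersion <- function(curve, model = c("voigt", "maxwell", "zener"),
                           rho = 1000, weights = c("none", "inverse_variance")) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  stopifnot(inherits(curve, "dispersion_curve"))
  n_min <- if (model == "zener") 4L else 3L
  if (nrow(curve) < n_min)
    stop("need at least ", n_min, " points to fit a ", model, " model")
  f <- curve$freq_hz
  cobs <- curve$c_mps
  w <- rep(1, length(f))
  if (weights == "inverse_variance") {
    sd <- curve$c_sd_mps
    if (anyNA(sd) || any(sd <= 0))
      stop("inverse_variance weighting requires positive c_sd_mps everywhere")
    w <- 1 / sd^2
  }

  lower <- c(mu = 1e-2, eta = 0)
  upper <- c(mu = 1e5, eta = 100)
  if (model == "zener") {
    lower <- c(lower, mu2 = 1e-2)
    upper <- c(upper, mu2 = 1e5)
  }

  cmodel <- function(p, freq) {
    pars <- rheo_params(model, mu = p[["mu"]], eta = p[["eta"]],
                        mu2 = if (model == "zener") p[["mu2"]] else NULL)
    g <- complex_modulus(pars, freq)
    # Maxwell G' -> 0 at low frequency; clamp so the objective stays finite
    phase_velocity_from_modulus(pmax(g$g_storage, 1e-12), g$g_loss, rho)
  }
  obj <- function(p) sum(w * (cobs - cmodel(p, f))^2)

  # deterministic multi-start across decades
  mu0 <- c(1e2, 1e3, 1e4)
  eta0 <- c(0.1, 1, 10)
  starts <- expand.grid(mu = mu0, eta = eta0, KEEP.OUT.ATTRS = FALSE)
  if (model == "zener") starts$mu2 <- starts$mu

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- unlist(starts[i, , drop = TRUE])
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 &&
         res$par[["eta"]] < best$par[["eta"]])) {
      best <- res
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  # polish from the winner
  pol <- tryCatch(
    stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 1000L, factr = 1e1)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) best <- pol

  rss <- best$value
  tss <- sum(w * (cobs - stats::weighted.mean(cobs, w))^2)
  r2 <- if (tss <= .Machine$double.eps * sum(w * cobs^2)) NA_real_
        else 1 - rss / tss
  params <- rheo_params(model, mu = best$par[["mu"]], eta = best$par[["eta"]],
                        mu2 = if (model == "zener") best$par[["mu2"]] else NULL)
  structure(list(params = params, r2 = r2, rss = rss,
                 converged = best$convergence == 0L,
                 n_points = length(f)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s: mu = %.4g Pa, eta = %.4g Pa.s%s | R2 = %.4f, RSS = %.3g, n = %d%s\n",
    x$params$model, x$params$mu, x$params$eta,
    if (!is.null(x$params$mu2)) sprintf(", mu2 = %.4g Pa", x$params$mu2) else "",
    x$r2, x$rss, x$n_points,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `fit_result` from [fit_dispersion].
#' @param path File path; `NULL` returns the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  x <- list(model = fit$params$model, mu_pa = fit$params$mu,
            eta_pas = fit$params$eta, mu2_pa = fit$params$mu2,
            r2 = fit$r2, rss = fit$rss, converged = fit$converged,
            n_points = fit$n_points)
  x <- x[!vapply(x, is.null, logical(1))]
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
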