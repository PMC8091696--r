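#' Phase velocity dispersion curve
#'
#' The central exchange object between the SWE pipeline, the DMA analysis and
#' the model fitting: phase velocity versus frequency, with optional per-point
#' spread, tagged by measurement band.
#'
#' @param freqs Strictly increasing frequencies, Hz.
#' @param c Phase velocity per frequency, m/s (> 0).
#' @param c_sd Optional per-point standard deviation, m/s.
#' @param band One of `"dma"`, `"swe"`, `"combined"`.
#' @return A `dispersion_curve`, which is a data.frame with columns
#'   `freq_hz`, `c_mps`, `c_sd_mps` and attribute `band`.
#' @export
dispersion_curve <- function(freqs, c, c_sd = NULL,
                             band = c("swe", "dma", "combined")) {
  band <- match.arg(band)
  stopifnot(length(freqs) == length(c), length(freqs) >= 1L,
            all(diff(freqs) > 0), all(c > 0), all(is.finite(c)))
  if (is.null(c_sd)) c_sd <- rep(NA_real_, length(freqs))
  stopifnot(length(c_sd) == length(freqs))
  out <- data.frame(freq_hz = as.numeric(freqs), c_mps = as.numeric(c),
                    c_sd_mps = as.numeric(c_sd))
  attr(out, "band") <- band
  class(out) <- c("dispersion_curve", "data.frame")
  out
}

#' @export
print.dispersion_curve <- function(x, ...) {
  cat(sprintf("<dispersion_curve> band = %s, %d points, %g-%g Hz\n",
              attr(x, "band"), nrow(x), min(x$freq_hz), max(x$freq_hz)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Model-predicted dispersion curve
#'
#' Forward-generate the phase-velocity curve of a rheological model on a
#' frequency grid (via the complex modulus).
#'
#' @param params A [rheo_params] object.
#' @param freqs Frequencies, Hz.
#' @param rho Mass density, kg/m^3.
#' @param band Band tag for the resulting curve.
#' @return A [dispersion_curve].
#' @export
model_dispersion <- function(params, freqs, rho = 1000, band = "swe") {
  g <- complex_modulus(params, freqs)
  dispersion_curve(freqs, phase_velocity_from_modulus(g$g_storage, g$g_loss, rho),
                   band = band)
}

#' Write / read a dispersion curve as CSV
#'
#' Columns: `freq_hz, c_mps, c_sd_mps`; the band tag is stored in a
#' `# band:` comment line.
#'
#' @param curve A [dispersion_curve].
#' @param path File path.
#' @return `read_curve_csv` returns a [dispersion_curve];
#'   `write_curve_csv` returns `path` invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "dispersion_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# band: %s", attr(curve, "band")), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  first <- readLines(path, n = 1L)
  band <- if (startsWith(first, "# band:")) trimws(sub("# band:", "", first))
          else "swe"
  df <- utils::read.csv(path, comment.char = "#")
  dispersion_curve(df$freq_hz, df$c_mps, df$c_sd_mps, band = band)
}

#' Complex modulus sweep container
#'
#' Storage and loss moduli on a frequency grid, the DMA-side analogue of a
#' [dispersion_curve].
#'
#' @param freqs Frequencies, Hz (strictly increasing).
#' @param g_storage Storage modulus G', Pa (> 0).
#' @param g_loss Loss modulus G'', Pa (>= 0).
#' @return A `modulus_sweep` data.frame with columns
#'   `freq_hz, g_storage_pa, g_loss_pa`.
#' @export
modulus_sweep <- function(freqs, g_storage, g_loss) {
  stopifnot(length(freqs) == length(g_storage),
            length(freqs) == length(g_loss),
            all(diff(freqs) > 0), all(g_storage > 0), all(g_loss >= 0))
  out <- data.frame(freq_hz = as.numeric(freqs),
                    g_storage_pa = as.numeric(g_storage),
                    g_loss_pa = as.numeric(g_loss))
  class(out) <- c("modulus_sweep", "data.frame")
  out
}
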