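#' Merge DMA and SWE dispersion curves
#'
#' Concatenates a low-frequency (DMA, 1--41 Hz) and a high-frequency (SWE,
#' 160--380 Hz) phase-velocity curve into one combined 1--380 Hz curve,
#' sorted by frequency, with per-point spreads carried through. The two
#' bands must not share frequencies (no averaging rule is defined for
#' duplicates).
#'
#' @param dma_curve A [dispersion_curve] with band `"dma"`.
#' @param swe_curve A [dispersion_curve] with band `"swe"`.
#' @return A [dispersion_curve] with band `"combined"`.
#' @export
merge_curves <- function(dma_curve, swe_curve) {
  stopifnot(inherits(dma_curve, "dispersion_curve"),
            inherits(swe_curve, "dispersion_curve"))
  if (attr(dma_curve, "band") != "dma" || attr(swe_curve, "band") != "swe")
    stop("merge_curves expects one dma-band and one swe-band curve")
  if (nrow(dma_curve) == 0 || nrow(swe_curve) == 0)
    stop("both curves must be non-empty")
  if (length(intersect(dma_curve$freq_hz, swe_curve$freq_hz)) > 0)
    stop("curves share frequencies; no averaging rule is defined")
  df <- rbind(as.data.frame(dma_curve), as.data.frame(swe_curve))
  df <- df[order(df$freq_hz), ]
  dispersion_curve(df$freq_hz, df$c_mps, df$c_sd_mps, band = "combined")
}

#' Combined-band Voigt estimate
#'
#' The wide-band analysis: merge the DMA and SWE dispersion curves and fit a
#' single Voigt model over 1--380 Hz. When only one band is supplied the
#' function falls back to a plain single-band fit with a warning.
#'
#' @param dma_curve,swe_curve [dispersion_curve]s (either may be `NULL`).
#' @param rho Mass density, kg/m^3.
#' @param weights Passed to [fit_dispersion].
#' @return A `fit_result` with the merged curve attached as `$curve` and a
#'   per-band residual split in `$band_rss` (sum of squared velocity
#'   residuals within each band).
#' @export
combined_estimate <- function(dma_curve, swe_curve, rho = 1000,
                              weights = "none") {
  if (is.null(dma_curve) || is.null(swe_curve)) {
    warning("only one band supplied; fitting it alone")
    curve <- dma_curve %||% swe_curve
    fit <- fit_dispersion(curve, "voigt", rho = rho, weights = weights)
    fit$curve <- curve
    return(fit)
  }
  curve <- merge_curves(dma_curve, swe_curve)
  fit <- fit_dispersion(curve, "voigt", rho = rho, weights = weights)
  fit$curve <- curve
  pred <- model_dispersion(fit$params, curve$freq_hz, rho)$c_mps
  res2 <- (curve$c_mps - pred)^2
  in_dma <- curve$freq_hz %in% dma_curve$freq_hz
  fit$band_rss <- c(dma = sum(res2[in_dma]), swe = sum(res2[!in_dma]))
  fit
}
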