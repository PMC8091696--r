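test_that("noiseless Voigt round trip recovers parameters on the DMA grid", {
  truth <- rheo_params("voigt", 1390, 6.27)
  curve <- model_dispersion(truth, dma_default_freqs(), band = "dma")
  fit <- fit_dispersion(curve, "voigt")
  expect_true(fit$converged)
  expect_lt(abs(fit$params$mu - 1390) / 1390, 1e-3)
  expect_lt(abs(fit$params$eta - 6.27) / 6.27, 1e-3)
  expect_gt(fit$r2, 0.9999)
})

test_that("elastic (constant) curves yield near-zero viscosity and NA r2", {
  freqs <- seq(160, 380, 20)
  curve <- dispersion_curve(freqs, rep(sqrt(1500 / 1000), length(freqs)),
                            band = "swe")
  fit <- fit_dispersion(curve, "voigt")
  expect_lte(fit$params$eta, 1e-3)
  expect_lt(abs(fit$params$mu - 1500) / 1500, 0.01)
  expect_true(is.na(fit$r2))    # zero total sum of squares
})

test_that("Maxwell fits Voigt-generated data worse than Voigt does", {
  truth <- rheo_params("voigt", 1200, 3)
  curve <- model_dispersion(truth, seq(1, 380, length.out = 25))
  r2_v <- fit_dispersion(curve, "voigt")$r2
  r2_m <- fit_dispersion(curve, "maxwell")$r2
  expect_gt(r2_v, r2_m)
})

test_that("Zener fit degenerates to Voigt behavior for a stiff second spring", {
  freqs <- seq(1, 380, length.out = 30)
  pv <- rheo_params("voigt", 1000, 2)
  pz <- rheo_params("zener", 1000, 2, mu2 = 1e6 * 1000)
  cv <- model_dispersion(pv, freqs)$c_mps
  cz <- model_dispersion(pz, freqs)$c_mps
  expect_lt(max(abs(cz / cv - 1)), 0.005)
})

test_that("parameter recovery under 1% multiplicative noise stays within 5%", {
  truth <- rheo_params("voigt", 1120, 5.40)
  base <- model_dispersion(truth, dma_default_freqs(), band = "dma")
  errs <- sapply(1:30, function(s) {
    set.seed(s)
    noisy <- dispersion_curve(base$freq_hz,
                              base$c_mps * (1 + stats::rnorm(9, sd = 0.01)),
                              band = "dma")
    fit <- fit_dispersion(noisy, "voigt")
    c(abs(fit$params$mu - 1120) / 1120, abs(fit$params$eta - 5.40) / 5.40)
  })
  expect_lt(stats::median(errs[1, ]), 0.05)
  expect_lt(stats::median(errs[2, ]), 0.05)
})

test_that("degenerate inputs are rejected", {
  short <- dispersion_curve(c(10, 20), c(1, 1.1), band = "dma")
  expect_error(fit_dispersion(short, "voigt"), "at least 3")
  three <- dispersion_curve(c(10, 20, 30), c(1, 1.1, 1.2), band = "dma")
  expect_error(fit_dispersion(three, "zener"), "at least 4")
})

test_that("inverse-variance weighting pulls the fit toward precise points", {
  truth <- rheo_params("voigt", 1000, 4)
  freqs <- dma_default_freqs()
  cc <- model_dispersion(truth, freqs)$c_mps
  cc[9] <- cc[9] * 1.3                      # corrupt one point
  sd <- rep(0.001, 9); sd[9] <- 1           # but flag it as imprecise
  curve <- dispersion_curve(freqs, cc, c_sd = sd, band = "dma")
  fw <- fit_dispersion(curve, "voigt", weights = "inverse_variance")
  fu <- fit_dispersion(curve, "voigt", weights = "none")
  err_w <- abs(fw$params$mu - 1000) / 1000
  err_u <- abs(fu$params$mu - 1000) / 1000
  expect_lt(err_w, err_u)
  expect_lt(err_w, 0.01)
})

test_that("fit results serialize to JSON and back", {
  fit <- fit_dispersion(model_dispersion(rheo_params("voigt", 900, 1),
                                         seq(160, 380, 20)), "voigt")
  path <- tempfile(fileext = ".json")
  write_fit_json(fit, path)
  x <- jsonlite::read_json(path)
  expect_equal(x$model, "voigt")
  expect_equal(x$mu_pa, fit$params$mu, tolerance = 1e-12)
  expect_true(x$converged)
})
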