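test_that("shape factor follows the cross-section-over-thickness rule", {
  expect_equal(shape_factor(specimen_geometry()), 0.01875)
  a <- 0.007
  expect_equal(shape_factor(specimen_geometry(a, a, a)), a)
  g1 <- specimen_geometry(0.005, 0.015, 0.004)
  g2 <- specimen_geometry(0.005, 0.015, 0.008)
  expect_equal(shape_factor(g2), shape_factor(g1) / 2)
})

test_that("moduli conversion handles the elastic and viscous extremes", {
  g <- specimen_geometry()          # SF = 0.01875 m
  el <- moduli_from_raw(dma_raw_sweep(c(1, 6), rep(187.5, 2), rep(0, 2), g))
  expect_equal(el$g_storage_pa, rep(10000, 2))
  expect_equal(el$g_loss_pa, rep(0, 2))

  visc <- moduli_from_raw(dma_raw_sweep(c(1, 6), rep(187.5, 2),
                                        rep(pi / 2 - 1e-9, 2), g))
  expect_lt(max(visc$g_storage_pa), 1e-3)
  expect_equal(visc$g_loss_pa, rep(10000, 2), tolerance = 1e-9)

  expect_error(dma_raw_sweep(c(1, 6), rep(187.5, 2), c(0.1, pi / 2)), "delta")
})

test_that("storage and loss moduli satisfy the Pythagorean identity", {
  set.seed(3)
  g <- specimen_geometry()
  sf <- shape_factor(g)
  for (i in 1:50) {
    stiff <- stats::runif(9, 50, 500)
    delta <- stats::runif(9, 0, pi / 2 - 0.01)
    m <- moduli_from_raw(dma_raw_sweep(dma_default_freqs(), stiff, delta, g))
    expect_equal(m$g_storage_pa^2 + m$g_loss_pa^2, (stiff / sf)^2,
                 tolerance = 1e-10)
  }
})

test_that("loss tangent is invariant to specimen geometry", {
  p <- rheo_params("voigt", 1120, 5.40)
  s1 <- simulate_dma_sweep(p, specimen_geometry())
  s2 <- simulate_dma_sweep(p, specimen_geometry(0.01, 0.02, 0.003))
  m1 <- moduli_from_raw(s1); m2 <- moduli_from_raw(s2)
  expect_equal(m1$g_loss_pa / m1$g_storage_pa,
               m2$g_loss_pa / m2$g_storage_pa, tolerance = 1e-10)
})

test_that("the default sweep grid is 1 to 41 Hz in 5 Hz steps", {
  expect_equal(dma_default_freqs(), c(1, 6, 11, 16, 21, 26, 31, 36, 41))
  expect_length(dma_default_freqs(), 9)
})

test_that("Voigt-consistent moduli reproduce the analytic dispersion", {
  mu <- 1120; eta <- 5.40
  f <- dma_default_freqs()
  m <- modulus_sweep(f, rep(mu, 9), 2 * pi * f * eta)
  cv <- dma_dispersion(m)
  expect_equal(cv$c_mps, voigt_phase_velocity(mu, eta, 1000, f),
               tolerance = 1e-12)
  expect_equal(attr(cv, "band"), "dma")

  flat <- dma_dispersion(modulus_sweep(f, rep(2000, 9), rep(0, 9)))
  expect_equal(flat$c_mps, rep(sqrt(2), 9))
})

test_that("noiseless simulate -> moduli -> fit round trip is exact", {
  p <- rheo_params("voigt", 1120, 5.40)
  fit <- dma_estimate(simulate_dma_sweep(p))
  expect_lt(abs(fit$params$mu - 1120) / 1120, 1e-3)
  expect_lt(abs(fit$params$eta - 5.40) / 5.40, 1e-3)

  s1 <- simulate_dma_sweep(p, noise_rel = 0.01, seed = 5L)
  s2 <- simulate_dma_sweep(p, noise_rel = 0.01, seed = 5L)
  expect_identical(s1$stiffness_ratio, s2$stiffness_ratio)
})

test_that("1% instrument noise keeps median recovery inside 5%", {
  p <- rheo_params("voigt", 1120, 5.40)
  errs <- sapply(1:50, function(s) {
    fit <- dma_estimate(simulate_dma_sweep(p, noise_rel = 0.01, seed = s))
    c(abs(fit$params$mu - 1120) / 1120, abs(fit$params$eta - 5.40) / 5.40)
  })
  expect_lt(stats::median(errs[1, ]), 0.05)
  expect_lt(stats::median(errs[2, ]), 0.05)
})

test_that("raw sweeps round-trip through CSV with geometry sidecar", {
  p <- rheo_params("voigt", 1250, 5.77)
  sw <- simulate_dma_sweep(p, specimen_geometry(0.006, 0.012, 0.005),
                           noise_rel = 0.02, seed = 9L)
  path <- tempfile(fileext = ".csv")
  write_dma_csv(sw, path)
  back <- read_dma_csv(path)
  expect_equal(back$stiffness_ratio, sw$stiffness_ratio, tolerance = 1e-12)
  expect_equal(back$delta, sw$delta, tolerance = 1e-12)
  expect_equal(back$geometry$thickness, 0.005)
})
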