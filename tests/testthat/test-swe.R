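test_that("autocorrelation velocity estimator inverts the IQ model", {
  p <- rheo_params("voigt", 860, 0.77)
  cfg <- acq_config(n_frames = 20)
  mov <- simulate_planar_wave(p, config = cfg)

  # constant-phase IQ -> zero velocity
  z <- mov; z$v[] <- 0
  vz <- iq_to_particle_velocity(velocity_to_iq(z))
  expect_lt(max(abs(vz$v)), 1e-12)

  # constant velocity -> recovered within 0.1%
  cv <- mov; cv$v[] <- 0.004
  vr <- iq_to_particle_velocity(velocity_to_iq(cv))
  expect_lt(max(abs(vr$v - 0.004) / 0.004), 1e-3)

  # propagating wave -> normalized RMSE < 2% (frames with a lag-1 estimate)
  full <- simulate_planar_wave(p)
  rec <- iq_to_particle_velocity(velocity_to_iq(full), kernel = 1L)
  sel <- 2:dim(full$v)[3]
  nrmse <- sqrt(mean((rec$v[, , sel] - full$v[, , sel])^2)) /
    sqrt(mean(full$v[, , sel]^2))
  expect_lt(nrmse, 0.02)

  expect_error(iq_to_particle_velocity(full), "no IQ")
})

test_that("despeckling preserves structure and kills spikes", {
  cfg <- acq_config(n_frames = 5)
  base <- simulate_planar_wave(rheo_params("voigt", 860, 0.77), config = cfg)

  const <- base; const$v[] <- 1.5
  out <- despeckle(const)
  expect_equal(out$v, const$v, tolerance = 1e-12)

  spike <- base; spike$v[] <- 0; spike$v[50, 70, 3] <- 1
  outs <- despeckle(spike)
  expect_lte(max(abs(outs$v)), 1 / 10)

  # planar (z-invariant) fields stay z-invariant
  outp <- despeckle(base)
  expect_lt(max(abs(outp$v[30, , ] - outp$v[60, , ])), 1e-12)

  tiny <- base; tiny$v <- base$v[1:2, 1:2, , drop = FALSE]
  expect_error(despeckle(tiny), "smaller")
})

test_that("temporal interpolation reproduces smooth signals", {
  cfg <- acq_config(n_frames = 50)
  m <- simulate_planar_wave(rheo_params("voigt", 860, 0.77), config = cfg)

  expect_identical(temporal_interpolate(m, 1L)$v, m$v)

  # linear ramp is reproduced exactly
  ramp <- m
  ramp$v <- aperm(array(rep(seq(0, 1, length.out = 50),
                            each = cfg$n_z * cfg$n_x),
                        c(cfg$n_z, cfg$n_x, 50)), c(1, 2, 3))
  ri <- temporal_interpolate(ramp, 5L)
  expect_equal(dim(ri$v)[3], 5 * 49 + 1)
  expect_equal(ri$v[1, 1, ], seq(0, 1, length.out = 5 * 49 + 1),
               tolerance = 1e-12)

  # 300 Hz sinusoid at 10 kHz sampling: max error < 1e-4 of amplitude
  sine <- m
  ts <- cfg$t
  sine$v <- aperm(array(rep(sin(2 * pi * 300 * ts),
                            each = cfg$n_z * cfg$n_x),
                        c(cfg$n_z, cfg$n_x, 50)), c(1, 2, 3))
  si <- temporal_interpolate(sine, 5L)
  expect_equal(dim(si$v)[3], 246)
  tfine <- si$config$t
  expect_lt(max(abs(si$v[1, 1, ] - sin(2 * pi * 300 * tfine))), 1e-4)
  # original samples preserved
  expect_equal(si$v[1, 1, seq(1, 246, by = 5)], sine$v[1, 1, ],
               tolerance = 1e-12)
})

test_that("band conditioning drops reverberation frames and low-passes", {
  cfg <- acq_config(n_frames = 50)
  m <- simulate_planar_wave(rheo_params("voigt", 860, 0.77), config = cfg)
  tone <- function(f) {
    x <- m
    x$v <- aperm(array(rep(sin(2 * pi * f * cfg$t), each = cfg$n_z * cfg$n_x),
                       c(cfg$n_z, cfg$n_x, 50)), c(1, 2, 3))
    x
  }
  pc <- pipeline_config(reverb_frames_dropped = 0)
  in_band <- band_condition(tone(300), pc)
  expect_equal(dim(in_band$v)[3], 50)
  expect_equal(stats::sd(in_band$v[1, 1, ]), stats::sd(tone(300)$v[1, 1, ]),
               tolerance = 0.01)
  out_band <- band_condition(tone(2000), pc)
  atten <- stats::sd(out_band$v[1, 1, 10:40]) / stats::sd(tone(2000)$v[1, 1, 10:40])
  expect_lt(20 * log10(atten), -20)

  pc2 <- pipeline_config(reverb_frames_dropped = 2)
  dropped <- band_condition(tone(300), pc2)
  expect_equal(dim(dropped$v)[3], 48)
})

test_that("directional filter separates wave directions exactly on-grid", {
  cfg <- acq_config()   # 50 frames @ 10 kHz -> 200 Hz grid
  fw <- steady_wave_movie(c(200, 400, 600), c(1, 0.7, 0.4), c0 = 1.5,
                          config = cfg)
  bw <- steady_wave_movie(c(200, 400, 600), c(1, 0.7, 0.4), c0 = 1.5,
                          config = cfg, sign = -1)
  sup <- fw; sup$v <- fw$v + bw$v

  ff <- directional_filter(fw)
  expect_lt(ff$backward_fraction, 1e-20)
  expect_gt(stats::cor(as.vector(ff$v), as.vector(fw$v)), 0.999)

  fb <- directional_filter(bw)
  expect_equal(fb$backward_fraction, 1, tolerance = 1e-12)
  expect_lt(sum(fb$v^2) / sum(bw$v^2), 0.05)

  fs <- directional_filter(sup)
  expect_equal(fs$backward_fraction, 0.5, tolerance = 1e-10)
  expect_gt(stats::cor(as.vector(fs$v), as.vector(fw$v)), 0.99)
})

test_that("adaptive threshold leaves forward-only transients untouched", {
  p <- rheo_params("voigt", 860, 0.77)
  mov <- simulate_planar_wave(p)
  pc <- pipeline_config()
  m <- band_condition(temporal_interpolate(despeckle(mov, pc),
                                           pc$interp_factor), pc)
  out <- directional_filter(m)
  expect_lt(out$backward_fraction, 0.25)
  expect_identical(out$v, m$v)
})

test_that("phase regression recovers a nondispersive velocity exactly", {
  cfg <- acq_config(n_frames = 500)       # 20 Hz grid covers the band
  mov <- steady_wave_movie(seq(160, 380, 20), rep(1, 12), c0 = 2.0,
                           config = cfg)
  mov$gate <- rep(TRUE, cfg$n_x)
  pc <- pipeline_config(interp_factor = 1, reverb_frames_dropped = 0)
  cv <- phase_velocity_spectrum(mov, pc)
  expect_equal(nrow(cv), 12)
  expect_lt(max(abs(cv$c_mps - 2) / 2), 0.01)

  # amplitude invariance: doubling the field leaves the curve unchanged
  mov2 <- mov; mov2$v <- 2 * mov$v
  mov2$gate <- mov$gate
  cv2 <- phase_velocity_spectrum(mov2, pc)
  expect_equal(cv2$c_mps, cv$c_mps, tolerance = 1e-12)
})

test_that("noiseless Voigt movie yields the analytic dispersion curve", {
  p <- rheo_params("voigt", 1050, 0.79)
  mov <- simulate_planar_wave(p)
  fit <- swe_estimate(mov)
  truth <- voigt_phase_velocity(1050, 0.79, 1000, fit$curve$freq_hz)
  expect_lt(max(abs(fit$curve$c_mps - truth) / truth), 0.02)
  # determinism
  fit2 <- swe_estimate(mov)
  expect_identical(fit$params$mu, fit2$params$mu)
  expect_identical(fit$curve$c_mps, fit2$curve$c_mps)
})

test_that("SWE estimates are robust to 5% measurement noise", {
  p <- rheo_params("voigt", 860, 0.77)
  clean <- simulate_planar_wave(p)
  nsd <- default_noise_sd(clean)
  errs <- sapply(1:5, function(s) {
    mov <- simulate_planar_wave(p, noise_sd = nsd, seed = s)
    fit <- swe_estimate(mov)
    abs(fit$params$mu - 860) / 860
  })
  expect_lt(stats::median(errs), 0.15)
})
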