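test_that("spectrogram lines: stationary, modulated, and zero inputs", {
  spp <- 84L
  n <- spp * 400
  t <- 0:(n - 1)
  x <- 0.7 * cos(2 * pi * t / spp)
  sl <- spectrogram_lines(x, spp)
  expect_lt(max(abs(Mod(sl$lines[, 1]) - 0.7)), 1e-3 * 0.7)

  # slow amplitude ramp tracked within 1%
  ramp <- 1 + 0.5 * (t / n)
  slr <- spectrogram_lines(ramp * x, spp)
  centers <- sl$centers
  expected <- 0.7 * (1 + 0.5 * (centers - 1) / n)
  expect_lt(max(abs(Mod(slr$lines[, 1]) - expected) / expected), 0.01)

  expect_equal(max(Mod(spectrogram_lines(numeric(n), spp)$lines)), 0)
  expect_error(spectrogram_lines(x[1:100], spp, window_periods = 4), "longer")
  expect_error(spectrogram_lines(x, spp, harmonics = 50), "Nyquist")
})

test_that("susceptibility vs bias matches the analytic Langevin derivative", {
  # beta * drive amplitude = 0.3: inside the linear-probe regime the mode assumes
  cfg <- quick_bias_config()
  p <- particle_model(5.5e-7, beta = 0.3)
  run <- synthesize_biased_run(p, cfg, tf_default(cfg), bias_periods = 4,
                               noise_density = 0, feedthrough = NULL)
  m_est <- tf_correct(run$measurements[[1]]$rx_voltage, run$tf,
                      cfg$sampling_rate)
  lines <- spectrogram_lines(m_est, cfg$samples_per_period)
  sc <- susceptibility_vs_bias(lines, run$channels$bias_monitor, cfg,
                               discard_bias_periods = 1)
  # chi(H) = M_sat * beta * L'(beta*H)
  truth <- 5.5e-7 * 0.3 * langevin_deriv(0.3 * sc$bias_field)
  keep <- abs(sc$bias_field) <= 3 / 0.3
  expect_lt(max(abs(Re(sc$susceptibility[keep]) - truth[keep])) / max(truth),
            0.02)
  # even symmetry
  chi_i <- stats::approx(sc$bias_field, Re(sc$susceptibility),
                         xout = abs(sc$bias_field))$y
  expect_lt(max(abs(Re(sc$susceptibility) - chi_i), na.rm = TRUE), 0.03 * max(truth))
})

test_that("a linear particle gives a flat susceptibility", {
  cfg <- quick_bias_config(bias_amplitude = 20, drive_periods_per_bias = 500)
  p <- particle_model(1e-7, beta = 0.005)  # linear over the whole sweep
  run <- synthesize_biased_run(p, cfg, tf_default(cfg), bias_periods = 3,
                               noise_density = 0, feedthrough = NULL)
  m_est <- tf_correct(run$measurements[[1]]$rx_voltage, run$tf,
                      cfg$sampling_rate)
  lines <- spectrogram_lines(m_est, cfg$samples_per_period)
  sc <- susceptibility_vs_bias(lines, run$channels$bias_monitor, cfg,
                               discard_bias_periods = 1)
  chi <- Re(sc$susceptibility)
  expect_lt((max(chi) - min(chi)) / mean(chi), 0.01)
})

test_that("integrated susceptibility recovers the Langevin curve and beta", {
  cfg <- quick_bias_config()
  p <- particle_model(5.5e-7, beta = 0.3)
  run <- synthesize_biased_run(p, cfg, tf_default(cfg), bias_periods = 4,
                               noise_density = 1e-9)
  res <- analyze_magnetometry(run, discard_bias_periods = 1)
  mc <- res$curve
  truth <- 5.5e-7 * langevin(0.3 * mc$bias_field)
  truth <- truth - mean(truth)
  expect_lt(max(abs(mc$moment - truth)), 0.02 * 5.5e-7)
  expect_lt(abs(res$langevin_fit$beta - 0.3) / 0.3, 0.02)
  expect_lt(abs(res$langevin_fit$msat - 5.5e-7) / 5.5e-7, 0.02)

  # constant chi integrates to a line through the origin
  flat <- structure(list(bias_field = seq(-5, 5, by = 0.5),
                         susceptibility = rep(2 + 0i, 21)),
                    class = "suscept_curve")
  mline <- integrate_susceptibility(flat)
  expect_equal(mline$moment, 2 * mline$bias_field, tolerance = 1e-10)
})

test_that("fwhm: triangle exact, Langevin-derivative width, beta scaling", {
  tri <- structure(list(bias_field = seq(-4, 4, by = 0.1),
                        susceptibility = pmax(0, 2 - abs(seq(-4, 4, by = 0.1)))),
                   class = "suscept_curve")
  expect_equal(fwhm(tri), 2)  # half max 1 at |H| = 1

  # FWHM of L'(beta*H) is 2*x_half/beta with L'(x_half) = L'(0)/2
  x_half <- stats::uniroot(function(x) langevin_deriv(x) - 1 / 6, c(1, 5),
                           tol = 1e-12)$root
  mk <- function(beta) {
    h <- seq(-8 / beta, 8 / beta, length.out = 1601)
    structure(list(bias_field = h, susceptibility = langevin_deriv(beta * h)),
              class = "suscept_curve")
  }
  expect_lt(abs(fwhm(mk(1)) - 2 * x_half), 0.01)
  expect_lt(abs(fwhm(mk(2)) - x_half), 0.005)  # beta x2 halves the width

  bimodal <- structure(list(bias_field = seq(-4, 4, by = 0.1),
                            susceptibility = abs(sin(seq(-4, 4, by = 0.1)))),
                       class = "suscept_curve")
  expect_error(fwhm(bimodal), "unimodal")
})

test_that("system matrix has Langevin harmonic symmetries and matches magnetometry", {
  cfg <- quick_bias_config(drive_amplitude = 10)
  p <- particle_model(5.5e-7, beta = 1)
  run <- synthesize_biased_run(p, cfg, tf_default(cfg), bias_periods = 3,
                               noise_density = 0)
  sm <- analyze_system_matrix(run, K = 7, discard_bias_periods = 1)

  # odd harmonics even in bias; even harmonics odd (vanish at zero bias)
  b <- sm$bias_field
  for (k in c(1, 3, 5)) {
    mk <- stats::approx(b, sm$magnitude[, k], xout = -b)$y
    ok <- !is.na(mk)
    expect_lt(max(abs(sm$magnitude[ok, k] - mk[ok])),
              0.03 * max(sm$magnitude[, k]))
  }
  for (k in c(2, 4)) {
    at0 <- stats::approx(b, sm$magnitude[, k], xout = 0)$y
    expect_lt(at0, 0.05 * max(sm$magnitude[, k]))
  }

  # zero particle gives a zero matrix
  p0 <- particle_model(0, beta = 1)
  run0 <- synthesize_biased_run(p0, cfg, tf_default(cfg), bias_periods = 3,
                                noise_density = 0, feedthrough = NULL)
  sm0 <- analyze_system_matrix(run0, K = 7, discard_bias_periods = 1)
  expect_lt(max(sm0$magnitude), 1e-12 * max(sm$magnitude))

  # fundamental row at low drive reproduces the susceptibility curve
  cfg_lo <- quick_bias_config(drive_amplitude = 1)
  run_lo <- synthesize_biased_run(p, cfg_lo, tf_default(cfg_lo),
                                  bias_periods = 3, noise_density = 0)
  p_lo <- particle_model(5.5e-7, beta = 0.3)
  run_lo <- synthesize_biased_run(p_lo, cfg_lo, tf_default(cfg_lo),
                                  bias_periods = 3, noise_density = 0)
  sm_lo <- analyze_system_matrix(run_lo, K = 3, discard_bias_periods = 1)
  chi_row <- sm_lo$magnitude[, 1] / cfg_lo$drive_amplitude
  truth <- 5.5e-7 * 0.3 * langevin_deriv(0.3 * sm_lo$bias_field)
  expect_lt(max(abs(chi_row - truth)), 0.02 * max(truth))
})

test_that("quasistatic pipeline agrees with a frozen-bias oracle", {
  cfg <- quick_bias_config(drive_amplitude = 10)
  p <- particle_model(5.5e-7, beta = 1)
  run <- synthesize_biased_run(p, cfg, tf_default(cfg), bias_periods = 3,
                               noise_density = 0)
  sm <- analyze_system_matrix(run, K = 7, discard_bias_periods = 1)

  hb_grid <- seq(-45, 45, by = 5)
  oracle <- sapply(1:7, function(k) k)  # placeholder dims
  oracle <- matrix(0, length(hb_grid), 7)
  for (i in seq_along(hb_grid)) {
    drv <- make_drive_waveform(cfg, periods = 4)
    frozen <- field_waveform(drv$samples + hb_grid[i], drv$sample_interval,
                             drv$period_samples)
    mo <- magnetization_response(frozen, p)
    oracle[i, ] <- Mod(harmonic_spectrum(mo, 84, K = 7))
  }
  for (k in 1:7) {
    got <- stats::approx(sm$bias_field, sm$magnitude[, k], xout = hb_grid)$y
    expect_lt(max(abs(got - oracle[, k])), 0.03 * max(oracle[, k]))
  }
})

test_that("biased runs are reproducible bit-for-bit under a fixed seed", {
  cfg <- quick_bias_config()
  p <- particle_model(5.5e-7, beta = 1)
  r1 <- synthesize_biased_run(p, cfg, tf_default(cfg), bias_periods = 2,
                              noise_density = 1e-8, seed = 17)
  r2 <- synthesize_biased_run(p, cfg, tf_default(cfg), bias_periods = 2,
                              noise_density = 1e-8, seed = 17)
  expect_identical(r1$measurements[[1]]$rx_voltage,
                   r2$measurements[[1]]$rx_voltage)
  expect_identical(r1$baseline, r2$baseline)
})
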