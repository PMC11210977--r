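# Noiseless, drift-free run shared across blocks
.noiseless_run <- function(periods = 10, msat = 5.5e-7) {
  cfg <- quick_config(periods = periods)
  p <- debye_particle(msat = msat)
  tf <- tf_default(cfg)
  run <- synthesize_in_out_run(p, cfg, tf,
                               drift = drift_model(0, 0),
                               noise_density = 0, seed = 2)
  list(run = run, cfg = cfg, particle = p, tf = tf)
}

test_that("harmonic extraction matches the particle spectrum exactly", {
  fx <- .noiseless_run()
  hs <- extract_harmonic_series(fx$run, K = 7)
  # constant across measurements of the same state
  in_rows <- hs$sample_state == "in"
  spread <- apply(hs$amplitudes[in_rows, ], 2, function(z) max(Mod(z - z[1])))
  expect_true(all(spread < 1e-10 * max(Mod(hs$amplitudes))))

  # consistent with harmonic_spectrum of the underlying moment (minus feedthrough)
  drv <- make_drive_waveform(fx$cfg)
  m <- magnetization_response(drv, fx$particle)
  truth <- harmonic_spectrum(m, 84, K = 7)
  diff_io <- hs$amplitudes[12, ] - hs$amplitudes[1, ]  # in minus out removes feedthrough
  expect_lt(max(Mod(diff_io - truth)) / max(Mod(truth)), 1e-6)
})

test_that("rolling average: constants, linear trends, variance reduction", {
  mk_series <- function(vals) {
    structure(list(amplitudes = matrix(vals, ncol = 1),
                   sample_state = rep(c("out", "in", "out", "in", "out"),
                                      each = 11),
                   index = 0:54, frequencies = 23809.5),
              class = "harmonic_series")
  }
  const <- mk_series(rep(3 + 2i, 55))
  expect_equal(rolling_average(const)$amplitudes, const$amplitudes)

  # interior points of a linear series are preserved per segment
  lin <- mk_series(complex(real = 0:54, imaginary = 2 * (0:54)))
  sm <- rolling_average(lin)
  expect_equal(sm$amplitudes[3:9, 1], lin$amplitudes[3:9, 1], tolerance = 1e-12)

  # ~5x variance reduction at interior points
  set.seed(12)
  vr <- replicate(300, {
    s <- mk_series(complex(real = stats::rnorm(55), imaginary = stats::rnorm(55)))
    Re(rolling_average(s)$amplitudes[6, 1])
  })
  expect_lt(abs(stats::var(vr) * 5 - 1 / 5 * 5), 0.2)  # var ~ 1/5 within 20%

  expect_warning(rolling_average(mk_series(rep(1 + 0i, 55)), window = 13),
                 "shorter")
})

test_that("drift model anchors on first/last sample-out blocks and corrects", {
  cfg <- quick_config(periods = 10)
  p <- debye_particle()
  tf <- tf_default(cfg)

  # drift-free: slope consistent with zero
  run0 <- synthesize_in_out_run(p, cfg, tf, drift = drift_model(0, 0),
                                noise_density = 0, seed = 3)
  dm0 <- fit_drift_model(extract_harmonic_series(run0, K = 3))
  expect_lt(max(Mod(dm0$slope)), 1e-14)

  # injected default drift recovered within 15% on the fundamental
  run <- synthesize_in_out_run(p, cfg, tf, drift = drift_model(),
                               noise_density = 1e-10, seed = 3)
  hs <- extract_harmonic_series(run, K = 1)
  dm <- fit_drift_model(hs)
  ft_amp <- Mod(hs$amplitudes[1, 1])
  expect_lt(abs(Mod(dm$slope[1]) / ft_amp - 1e-5 * sqrt(2)) / (1e-5 * sqrt(2)),
            0.15)

  # residual after drift removal is at the noise level
  corrected <- remove_drift(hs, dm)
  out_rows <- corrected$sample_state == "out"
  resid_sd <- stats::sd(Re(corrected$amplitudes[out_rows, 1]))
  # per-component bin noise for this record length and tf
  n <- 84 * 10
  sigma_amp <- 1e-10 * sqrt(cfg$sampling_rate / 2) * sqrt(2 / n) /
    Mod(tf_eval(tf, cfg$drive_frequency))
  expect_lt(resid_sd, sigma_amp * 1.5)

  expect_error(fit_drift_model(extract_harmonic_series(run, K = 1),
                               n_anchor = 30), "sample-out")
})

test_that("GLM equals the normal-equations oracle and nulls exact trends", {
  fx <- .noiseless_run()
  hs <- extract_harmonic_series(fx$run, K = 5)
  res <- fit_glm(hs)

  # independent oracle: solve(X'X) X'y on real and imaginary stacks
  X <- cbind(1, hs$index - mean(hs$index),
             as.numeric(hs$sample_state == "in"))
  for (k in 1:5) {
    y <- hs$amplitudes[, k]
    beta <- solve(t(X) %*% X, t(X) %*% cbind(Re(y), Im(y)))
    oracle <- complex(real = beta[3, 1], imaginary = beta[3, 2])
    expect_lt(Mod(res$signal_amplitude[k] - oracle),
              1e-10 * max(Mod(y), 1e-300))
  }

  # noiseless recovery equals the particle's harmonic spectrum
  drv <- make_drive_waveform(fx$cfg)
  truth <- harmonic_spectrum(magnetization_response(drv, fx$particle), 84, K = 5)
  expect_lt(max(Mod(res$signal_amplitude - truth)) / max(Mod(truth)), 1e-8)

  # invariant to added constant and linear-in-index terms
  hs2 <- hs
  hs2$amplitudes <- hs2$amplitudes + (2 + 3i) +
    outer(hs2$index, rep(0.01 + 0.02i, 5))
  res2 <- fit_glm(hs2)
  # absolute scale set by the added O(1) terms
  expect_lt(max(Mod(res2$signal_amplitude - res$signal_amplitude)), 1e-12)
})

test_that("pipeline amplitude is proportional to particle mass", {
  cfg <- quick_config(periods = 5)
  tf <- tf_default(cfg)
  msats <- 5.5e-7 * 10^seq(-2, 1, by = 1)
  amps <- vapply(msats, function(ms) {
    run <- synthesize_in_out_run(debye_particle(msat = ms), cfg, tf,
                                 drift = drift_model(0, 0), noise_density = 0,
                                 seed = 2)
    Mod(fit_glm(extract_harmonic_series(run, K = 3))$signal_amplitude[3])
  }, numeric(1))
  fit <- stats::lm(amps ~ msats)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("in/out GLM rejects strong drift with modest variance inflation", {
  cfg <- quick_config(periods = 5)
  p <- debye_particle()
  tf <- tf_default(cfg)
  nd <- 1e-8
  # bin noise sd per component at the fundamental for this record
  n <- 84 * 5
  sigma <- nd * sqrt(cfg$sampling_rate / 2) * sqrt(2 / n) /
    Mod(tf_eval(tf, cfg$drive_frequency))
  # drift chosen so the per-measurement feedthrough step is ~10x sigma
  ft <- 7.5e-5
  rate <- 10 * sigma / ft
  sds <- vapply(1:30, function(s) {
    run <- synthesize_in_out_run(p, cfg, tf, drift = drift_model(rate, 0),
                                 noise_density = nd, seed = 1000 + s)
    fit_glm(remove_drift(extract_harmonic_series(run, K = 1)))$residual_sd[1]
  }, numeric(1))
  expect_lt(mean(sds), sigma * 1.2)
})

test_that("dilution sensitivity: exact series, recovery, homogeneity", {
  # exact linear series
  masses <- c(1, 2, 5, 10, 20, 50) * 1e-12
  slope <- 110
  res <- dilution_sensitivity(masses, slope * masses, rep(1e-12, 6))
  expect_equal(res$mass_at_snr1, 1e-12 / slope, tolerance = 1e-12)
  expect_equal(res$mass_at_snr5, 5e-12 / slope, tolerance = 1e-12)

  # doubling all signals halves the detection limit
  res2 <- dilution_sensitivity(masses, 2 * slope * masses, rep(1e-12, 6))
  expect_equal(res2$mass_at_snr1, res$mass_at_snr1 / 2, tolerance = 1e-12)

  # noisy recovery of a known injected sensitivity within 20%
  set.seed(31)
  errs <- replicate(25, {
    noise_sd <- 1e-12
    amps <- slope * masses + stats::rnorm(6, sd = noise_sd)
    r <- dilution_sensitivity(masses, amps, rep(noise_sd, 6))
    abs(r$mass_at_snr1 - noise_sd / slope) / (noise_sd / slope)
  })
  expect_lt(mean(errs), 0.2)

  expect_warning(r0 <- dilution_sensitivity(masses, -slope * masses,
                                            rep(1e-12, 6)), "slope")
  expect_false(r0$detectable)
  expect_error(dilution_sensitivity(masses[1:2], 1:2, 1:2), "3 dilution")
})
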