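# One-sided FFT bin frequencies for an n-sample record at rate fs
.bin_freqs <- function(n, fs) (0:(n %/% 2)) * fs / n

# Apply complex one-sided gains to a real signal; enforces conjugate symmetry
# so the output is exactly real. `gains` has length n %/% 2 + 1.
.apply_onesided <- function(x, gains) {
  n <- length(x)
  n2 <- n %/% 2
  X <- stats::fft(x)
  H <- X[1:(n2 + 1)] * gains
  if (n %% 2 == 0) H[n2 + 1] <- complex(real = Re(H[n2 + 1]), imaginary = 0)
  full <- complex(length.out = n)
  full[1:(n2 + 1)] <- H
  if (n2 >= 2) full[n:(n2 + 2)] <- Conj(H[2:n2])
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Acquisition configuration
#'
#' Timing contract of the instrument: 2 MHz sampling, a 42 us drive period
#' (23.8 kHz) commensurate with the sampling rate (84 samples per period, so
#' every period is sample-identical), and an 84 ms bias period holding
#' exactly 2000 drive periods.
#'
#' @param sampling_rate Samples per second (default 2e6).
#' @param drive_period Drive period (s, default 42e-6).
#' @param bias_period Bias period (s, default 84e-3).
#' @param drive_amplitude Drive field amplitude (mT peak, default 10).
#' @param bias_amplitude Bias field amplitude (mT peak, default 0;
#'   magnetometry and system-matrix modes use 50).
#' @param periods_per_measurement Drive periods acquired per spectroscopy
#'   measurement (default 2000, i.e. 84 ms).
#' @param random_seed Master seed for the run's noise streams.
#' @return An object of class `acq_config`.
#' @export
acq_config <- function(sampling_rate = 2e6, drive_period = 42e-6,
                       bias_period = 84e-3, drive_amplitude = 10,
                       bias_amplitude = 0, periods_per_measurement = 2000,
                       random_seed = 1L) {
  .check_pos(sampling_rate, "sampling_rate")
  .check_pos(drive_period, "drive_period")
  .check_pos(bias_period, "bias_period")
  .check_nonneg(drive_amplitude, "drive_amplitude")
  .check_nonneg(bias_amplitude, "bias_amplitude")
  spp <- sampling_rate * drive_period
  if (abs(spp - round(spp)) > 1e-9)
    stop("sampling_rate * drive_period must be an exact integer (samples per period)",
         call. = FALSE)
  dpb <- bias_period / drive_period
  if (abs(dpb - round(dpb)) > 1e-9)
    stop("bias_period must be an exact integer number of drive periods", call. = FALSE)
  if (periods_per_measurement < 1 ||
      periods_per_measurement != round(periods_per_measurement))
    stop("periods_per_measurement must be a positive integer", call. = FALSE)
  structure(list(sampling_rate = sampling_rate,
                 drive_period = drive_period,
                 bias_period = bias_period,
                 drive_frequency = 1 / drive_period,
                 bias_frequency = 1 / bias_period,
                 drive_amplitude = drive_amplitude,
                 bias_amplitude = bias_amplitude,
                 samples_per_period = as.integer(round(spp)),
                 samples_per_bias_period = as.integer(round(spp * dpb)),
                 drive_periods_per_bias_period = as.integer(round(dpb)),
                 periods_per_measurement = as.integer(periods_per_measurement),
                 random_seed = as.integer(random_seed)),
            class = "acq_config")
}

#' @export
print.acq_config <- function(x, ...) {
  cat(sprintf("Acquisition: fs = %g Hz, drive %g us (%0.1f kHz, %d samp/period), bias %g ms, %d periods/measurement\n",
              x$sampling_rate, x$drive_period * 1e6, x$drive_frequency / 1e3,
              x$samples_per_period, x$bias_period * 1e3, x$periods_per_measurement))
  cat(sprintf("  drive %g mT pk, bias %g mT pk\n", x$drive_amplitude, x$bias_amplitude))
  invisible(x)
}

#' Receive-chain transfer function
#'
#' Complex frequency response mapping a magnetic moment (Am^2) in the
#' receive coil to the voltage at the preamp output (V). Stored on a
#' frequency grid; intermediate frequencies are interpolated linearly in the
#' real and imaginary parts.
#'
#' @param frequency_grid Frequencies (Hz), strictly increasing.
#' @param response Complex response (V per Am^2), same length.
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(frequency_grid, response) {
  if (is.unsorted(frequency_grid, strictly = TRUE))
    stop("`frequency_grid` must be strictly increasing", call. = FALSE)
  if (length(frequency_grid) != length(response))
    stop("grid and response lengths differ", call. = FALSE)
  structure(list(frequency_grid = as.numeric(frequency_grid),
                 response = as.complex(response)),
            class = "transfer_function")
}

#' Evaluate a transfer function at arbitrary frequencies
#'
#' Linear interpolation in the real and imaginary parts; frequencies outside
#' the stored grid are an error.
#'
#' @param tf A [transfer_function()].
#' @param f Frequencies (Hz).
#' @return Complex response values.
#' @export
tf_eval <- function(tf, f) {
  stopifnot(inherits(tf, "transfer_function"))
  rng <- range(tf$frequency_grid)
  if (any(f < rng[1] - 1e-9 | f > rng[2] + 1e-9))
    stop("frequency outside transfer-function grid", call. = FALSE)
  re <- stats::approx(tf$frequency_grid, Re(tf$response), xout = f, rule = 2)$y
  im <- stats::approx(tf$frequency_grid, Im(tf$response), xout = f, rule = 2)$y
  complex(real = re, imaginary = im)
}

#' Parametric default receive transfer function
#'
#' Ideal Faraday differentiator (i 2 pi f) times a second-order notch at the
#' drive frequency (finite depth, default 30 dB) times a flat gain. The
#' notch compresses the feedthrough-dominated fundamental so the harmonics
#' fit the digitizer's dynamic range.
#'
#' @param config An [acq_config()]; sets the notch frequency and grid extent.
#' @param gain Flat gain (V s / Am^2), default 1.
#' @param notch_depth_db Notch depth at the drive frequency (dB, default 30).
#' @param notch_q Notch quality factor (default 2).
#' @param df Grid spacing (Hz, default 250).
#' @return A [transfer_function()].
#' @export
tf_default <- function(config, gain = 1, notch_depth_db = 30, notch_q = 2,
                       df = 250) {
  f <- seq(0, config$sampling_rate / 2, by = df)
  if (f[length(f)] < config$sampling_rate / 2)
    f <- c(f, config$sampling_rate / 2)
  w0 <- 2 * pi * config$drive_frequency
  s <- complex(imaginary = 2 * pi * f)
  b <- w0 / notch_q
  a <- b * 10^(-notch_depth_db / 20)
  notch <- (s^2 + a * s + w0^2) / (s^2 + b * s + w0^2)
  transfer_function(f, gain * complex(imaginary = 2 * pi * f) * notch)
}

#' Ideal differentiator transfer function on an explicit grid
#'
#' @param frequency_grid Frequencies (Hz), strictly increasing.
#' @param gain Flat gain (V s / Am^2).
#' @return A [transfer_function()] with response `gain * i 2 pi f`.
#' @export
tf_differentiator <- function(frequency_grid, gain = 1) {
  transfer_function(frequency_grid,
                    gain * complex(imaginary = 2 * pi * frequency_grid))
}

#' Per-measurement drift model
#'
#' Slow instability of the drive chain, quantified per measurement: the
#' default rates are 0.1 percent amplitude and 1 milliradian of phase per
#' 100 measurements. Drift is applied as a complex scalar on the moment
#' contribution (signal plus feedthrough) of each measurement.
#'
#' @param amplitude_rate Fractional amplitude change per measurement
#'   (default 1e-5 = 0.1 percent per 100).
#' @param phase_rate Phase change per measurement (rad, default 1e-5 =
#'   1 mrad per 100).
#' @param additive Optional complex per-harmonic additive baseline.
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(amplitude_rate = 1e-5, phase_rate = 1e-5,
                        additive = NULL) {
  if (!is.finite(amplitude_rate) || !is.finite(phase_rate))
    stop("drift rates must be finite", call. = FALSE)
  structure(list(amplitude_rate = amplitude_rate, phase_rate = phase_rate,
                 additive = additive),
            class = "drift_model")
}

#' Complex drift factor at a measurement index
#'
#' @param drift A [drift_model()].
#' @param index Zero-based measurement index (vectorized).
#' @return Complex scale factor(s).
#' @export
drift_factor <- function(drift, index) {
  stopifnot(inherits(drift, "drift_model"))
  (1 + drift$amplitude_rate)^index * exp(complex(imaginary = drift$phase_rate * index))
}

#' Drive-field waveform
#'
#' Cosine at the drive frequency, phase 0 at t = 0, with optional
#' third-harmonic contamination at a stated dBc level emulating residual
#' amplifier/filter distortion.
#'
#' @param config An [acq_config()].
#' @param periods Number of drive periods (default
#'   `config$periods_per_measurement`).
#' @param contamination_dbc Amplitude of the contamination harmonic relative
#'   to the fundamental (dBc); `NULL` (default) for a pure tone.
#' @param contamination_harmonic Harmonic order of the contamination (default 3).
#' @return A [field_waveform()] in mT with `period_samples` per drive period.
#' @export
make_drive_waveform <- function(config, periods = config$periods_per_measurement,
                                contamination_dbc = NULL,
                                contamination_harmonic = 3) {
  stopifnot(inherits(config, "acq_config"))
  spp <- config$samples_per_period
  n <- spp * periods
  ph <- 2 * pi * (seq_len(n) - 1) / spp
  h <- config$drive_amplitude * cos(ph)
  if (!is.null(contamination_dbc)) {
    h <- h + config$drive_amplitude * 10^(contamination_dbc / 20) *
      cos(contamination_harmonic * ph)
  }
  field_waveform(h, 1 / config$sampling_rate, spp)
}

#' Bias-field waveform
#'
#' Slow sinusoid (default 11.9 Hz) shifting the particles' quasistatic
#' operating point; sine phase so the record starts at zero field.
#'
#' @param config An [acq_config()].
#' @param bias_periods Number of bias periods.
#' @return A [field_waveform()] in mT with `period_samples` per bias period.
#' @export
make_bias_waveform <- function(config, bias_periods = 1) {
  stopifnot(inherits(config, "acq_config"))
  spb <- config$samples_per_bias_period
  n <- spb * bias_periods
  h <- config$bias_amplitude * sin(2 * pi * (seq_len(n) - 1) / spb)
  field_waveform(h, 1 / config$sampling_rate, spb)
}

#' Feedthrough specification
#'
#' Residual drive-field coupling modeled at f0 and (optionally) 3 f0, as an
#' equivalent moment seen by the receive coil.
#'
#' @param moment_f0 Equivalent feedthrough moment at the fundamental (Am^2);
#'   default 7.5e-5, the budget value for 250 A-turns, 3e-4 m^2, -60 dB
#'   gradiometer.
#' @param third_dbc Third-harmonic drive contamination relative to the
#'   fundamental (dBc); `-Inf` disables it.
#' @return An object of class `feedthrough_spec`.
#' @export
feedthrough_spec <- function(moment_f0 = 7.5e-5, third_dbc = -108) {
  .check_nonneg(moment_f0, "moment_f0")
  structure(list(moment_f0 = moment_f0, third_dbc = third_dbc),
            class = "feedthrough_spec")
}

# Feedthrough moment time series on the drive grid
.feedthrough_series <- function(ft, config, n) {
  if (is.null(ft)) return(numeric(n))
  spp <- config$samples_per_period
  ph <- 2 * pi * (seq_len(n) - 1) / spp
  out <- ft$moment_f0 * cos(ph)
  if (is.finite(ft$third_dbc))
    out <- out + ft$moment_f0 * 10^(ft$third_dbc / 20) * cos(3 * ph)
  out
}

#' Synthesize a receive-coil voltage record
#'
#' V(f) = TF(f) * [drift * (M(f) + feedthrough(f))] plus white Gaussian
#' noise. The moment is converted through the transfer function in the
#' frequency domain with conjugate symmetry enforced, so the voltage is
#' exactly real. Deterministic for a fixed seed.
#'
#' @param moment Sample moment time series (Am^2), real.
#' @param config An [acq_config()].
#' @param tf A [transfer_function()] covering DC to Nyquist.
#' @param noise_density White noise density at the preamp output
#'   (V/sqrt(Hz)); per-sample sd is `noise_density * sqrt(fs / 2)`.
#' @param drift Complex drift factor for this measurement (default 1).
#' @param feedthrough A [feedthrough_spec()] or `NULL`.
#' @param seed Optional integer seed for the noise draw.
#' @return Voltage time series (V), same length as `moment`.
#' @export
synthesize_rx <- function(moment, config, tf, noise_density = 0,
                          drift = 1 + 0i, feedthrough = NULL, seed = NULL) {
  stopifnot(inherits(config, "acq_config"), inherits(tf, "transfer_function"))
  n <- length(moment)
  m_tot <- moment + .feedthrough_series(feedthrough, config, n)
  gains <- tf_eval(tf, .bin_freqs(n, config$sampling_rate)) * drift
  v <- .apply_onesided(m_tot, gains)
  if (noise_density > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(n, sd = noise_density * sqrt(config$sampling_rate / 2))
  }
  v
}

# B-field monitor (two-turn dB/dt coil) gain, V per (mT/s)
BMON_GAIN <- 1e-6

# Drive coil sensitivity, mT per A (Table-level constant of the emulated coil)
DRIVE_COIL_SENS <- 0.5

# Analytic time derivative of drive + bias field (mT/s) on the record grid
.field_derivative <- function(config, n, bias = FALSE) {
  spp <- config$samples_per_period
  fs <- config$sampling_rate
  t_idx <- seq_len(n) - 1
  d <- -config$drive_amplitude * 2 * pi * config$drive_frequency *
    sin(2 * pi * t_idx / spp)
  if (bias && config$bias_amplitude > 0) {
    spb <- config$samples_per_bias_period
    d <- d + config$bias_amplitude * 2 * pi * config$bias_frequency *
      cos(2 * pi * t_idx / spb)
  }
  d
}

#' Synthesize a sample-in/out spectroscopy run
#'
#' Generates the full measurement schedule of the in/out spectroscopy mode:
#' blocks of 11 sample-out and 11 sample-in measurements in the pattern
#' out/in/out/in/out (55 measurements; the in/out cycle repeated 2.5 times,
#' beginning and ending sample-out). Every measurement carries the
#' feedthrough and noise; sample-in measurements additionally carry the
#' particle's steady-state response. Drift advances monotonically across the
#' whole run. Per-measurement noise streams are seeded from the master seed
#' plus the measurement index.
#'
#' @param particle A [particle_model()].
#' @param config An [acq_config()].
#' @param tf A [transfer_function()].
#' @param drift A [drift_model()].
#' @param noise_density Output-referred noise density (V/sqrt(Hz)).
#' @param feedthrough A [feedthrough_spec()] or `NULL`.
#' @param block_length Measurements per in/out block (default 11).
#' @param n_blocks Number of blocks (default 5: out, in, out, in, out).
#' @param seed Master seed; defaults to `config$random_seed`.
#' @return An `mps_run` container (see [write_run()]) with per-measurement
#'   receive voltages, shared noiseless monitor channels, and the full
#'   generation provenance.
#' @export
synthesize_in_out_run <- function(particle, config, tf,
                                  drift = drift_model(),
                                  noise_density = 0,
                                  feedthrough = feedthrough_spec(),
                                  block_length = 11, n_blocks = 5,
                                  seed = config$random_seed) {
  stopifnot(inherits(particle, "particle_model"))
  states <- rep(rep(c("out", "in"), length.out = n_blocks), each = block_length)
  n_meas <- length(states)
  drive <- make_drive_waveform(config)
  n <- length(drive$samples)
  moment_in <- magnetization_response(drive, particle)
  gains <- tf_eval(tf, .bin_freqs(n, config$sampling_rate))
  ftser <- .feedthrough_series(feedthrough, config, n)
  sdn <- noise_density * sqrt(config$sampling_rate / 2)
  measurements <- vector("list", n_meas)
  for (j in seq_len(n_meas)) {
    m <- if (states[j] == "in") moment_in + ftser else ftser
    v <- .apply_onesided(m, gains * drift_factor(drift, j - 1))
    if (sdn > 0) {
      set.seed(seed + j - 1L)
      v <- v + stats::rnorm(n, sd = sdn)
    }
    measurements[[j]] <- list(rx_voltage = v, sample_state = states[j],
                              index = j - 1L)
  }
  channels <- list(
    bmon = BMON_GAIN * .field_derivative(config, n),
    drive_monitor = (config$drive_amplitude / DRIVE_COIL_SENS) *
      cos(2 * pi * (seq_len(n) - 1) / config$samples_per_period),
    bias_monitor = numeric(n))
  new_run(config = config, particle = particle, tf = tf, drift = drift,
          noise_density = noise_density, feedthrough = feedthrough,
          seed = seed, mode = "spectroscopy",
          measurements = measurements, channels = channels)
}

#' Synthesize a biased (magnetometry / system-matrix) run
#'
#' One long acquisition with the drive field superposed on a slow bias
#' sinusoid; the particle's steady-state response is computed over the full
#' bias period (the record is an integer number of bias periods, so the
#' circular steady state is exact).
#'
#' @param particle A [particle_model()].
#' @param config An [acq_config()] with nonzero `bias_amplitude`.
#' @param tf A [transfer_function()].
#' @param bias_periods Number of bias periods in the record (default 24,
#'   about 2 s at the default timing).
#' @param noise_density Output-referred noise density (V/sqrt(Hz)).
#' @param feedthrough A [feedthrough_spec()] or `NULL`.
#' @param seed Noise seed; defaults to `config$random_seed`.
#' @return An `mps_run` container with a single long measurement, the bias
#'   monitor channel, and full provenance.
#' @export
synthesize_biased_run <- function(particle, config, tf, bias_periods = 24,
                                  noise_density = 0,
                                  feedthrough = feedthrough_spec(),
                                  seed = config$random_seed) {
  stopifnot(inherits(particle, "particle_model"))
  if (config$bias_amplitude <= 0)
    stop("biased run requires a nonzero bias amplitude", call. = FALSE)
  spb <- config$samples_per_bias_period
  n <- spb * bias_periods
  spp <- config$samples_per_period
  t_idx <- seq_len(n) - 1
  h_drive <- config$drive_amplitude * cos(2 * pi * t_idx / spp)
  h_bias <- config$bias_amplitude * sin(2 * pi * t_idx / spb)
  field <- field_waveform(h_drive + h_bias, 1 / config$sampling_rate, spb)
  moment <- magnetization_response(field, particle)
  v <- synthesize_rx(moment, config, tf, noise_density = noise_density,
                     feedthrough = feedthrough, seed = seed)
  baseline <- synthesize_rx(numeric(n), config, tf,
                            noise_density = noise_density,
                            feedthrough = feedthrough, seed = seed + 100003L)
  channels <- list(
    bmon = BMON_GAIN * .field_derivative(config, n, bias = TRUE),
    drive_monitor = (config$drive_amplitude / DRIVE_COIL_SENS) *
      cos(2 * pi * t_idx / spp),
    bias_monitor = h_bias)
  new_run(config = config, particle = particle, tf = tf, drift = NULL,
          noise_density = noise_density, feedthrough = feedthrough,
          seed = seed, mode = "biased",
          measurements = list(list(rx_voltage = v, sample_state = "in",
                                   index = 0L)),
          channels = channels, bias_periods = bias_periods,
          baseline = baseline)
}

#' Synthesize a transfer-function calibration sweep
#'
#' Emulates driving a known test coil (default 15 turns, 5 mm diameter)
#' with single-tone currents at harmonics of the drive frequency while
#' recording the receive voltage, for [measure_tf()].
#'
#' @param tf The true [transfer_function()] to emulate.
#' @param config An [acq_config()].
#' @param harmonics Harmonic orders of the drive frequency to sweep.
#' @param test_coil List with `turns` and `diameter` (m).
#' @param current_amplitude Peak current (A).
#' @param periods Drive periods per record (default 100).
#' @param noise_density Optional receive noise (V/sqrt(Hz)).
#' @param seed Noise seed.
#' @return List of records, each with `freq`, `current`, `rx_voltage`,
#'   `cycles`, plus the shared `test_coil`, `config`.
#' @export
synthesize_calibration_sweep <- function(tf, config, harmonics = 1:12,
                                         test_coil = list(turns = 15, diameter = 5e-3),
                                         current_amplitude = 1, periods = 100,
                                         noise_density = 0, seed = 1L) {
  stopifnot(inherits(tf, "transfer_function"), inherits(config, "acq_config"))
  area <- pi * (test_coil$diameter / 2)^2
  spp <- config$samples_per_period
  n <- spp * periods
  records <- vector("list", length(harmonics))
  for (i in seq_along(harmonics)) {
    k <- harmonics[i]
    cycles <- k * periods
    ph <- 2 * pi * cycles * (seq_len(n) - 1) / n
    current <- current_amplitude * cos(ph)
    moment <- test_coil$turns * current * area
    v <- synthesize_rx(moment, config, tf, noise_density = noise_density,
                       seed = seed + i)
    records[[i]] <- list(freq = k * config$drive_frequency, current = current,
                         rx_voltage = v, cycles = cycles)
  }
  structure(list(records = records, test_coil = test_coil, config = config),
            class = "calibration_sweep")
}
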