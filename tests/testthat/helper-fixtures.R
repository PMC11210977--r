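# Shared fixtures: small, fast configurations built in code.

# Default-timing config with a short acquisition (n drive periods / meas).
quick_config <- function(periods = 20, drive_amplitude = 10,
                         bias_amplitude = 0, seed = 1L) {
  acq_config(drive_amplitude = drive_amplitude,
             bias_amplitude = bias_amplitude,
             periods_per_measurement = periods, random_seed = seed)
}

# Biased-mode config. The default keeps the instrument's factor-2000
# drive/bias separation (the quasistatic approximation needs it: the bias
# must move < ~1 mT within one STFT window); tests keep records short by
# using few bias periods instead.
quick_bias_config <- function(drive_amplitude = 1, bias_amplitude = 50,
                              drive_periods_per_bias = 2000, seed = 1L) {
  acq_config(bias_period = drive_periods_per_bias * 42e-6,
             drive_amplitude = drive_amplitude,
             bias_amplitude = bias_amplitude, random_seed = seed)
}

# A mid-grid relaxing particle
debye_particle <- function(msat = 5.5e-7, beta = 1, tau = 2.5e-6) {
  particle_model(msat, beta = beta, kernel = "debye", tau_eff = tau)
}

# Transfer function with exact values on a record's DFT bins (differentiator)
exact_diff_tf <- function(n, fs = 2e6, gain = 1) {
  f <- (0:(n %/% 2)) * fs / n
  tf_differentiator(f, gain = gain)
}

expect_rel_equal <- function(actual, expected, rel) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), rel)
}
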