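#' Measure the receive transfer function from a calibration sweep
#'
#' TF(f) = V_rx(f) / (N * I(f) * A): at each swept frequency the complex
#' exact-bin amplitudes of the receive voltage and the test-coil current are
#' ratioed against the known coil geometry.
#'
#' @param sweep A [synthesize_calibration_sweep()] result (or equivalent
#'   structure from recorded data).
#' @return A [transfer_function()] on the swept frequency grid.
#' @export
measure_tf <- function(sweep) {
  stopifnot(inherits(sweep, "calibration_sweep"))
  area <- pi * (sweep$test_coil$diameter / 2)^2
  turns <- sweep$test_coil$turns
  freqs <- vapply(sweep$records, `[[`, numeric(1), "freq")
  resp <- vapply(sweep$records, function(rec) {
    n <- length(rec$current)
    bin <- rec$cycles + 1L
    i_amp <- 2 * stats::fft(rec$current)[bin] / n
    v_amp <- 2 * stats::fft(rec$rx_voltage)[bin] / n
    if (Mod(i_amp) == 0) stop("zero current at swept frequency", call. = FALSE)
    v_amp / (turns * i_amp * area)
  }, complex(1))
  ord <- order(freqs)
  transfer_function(freqs[ord], resp[ord])
}

#' Subtract a baseline record
#'
#' Pointwise difference of a measurement and a sample-out baseline acquired
#' with an identical pulse sequence.
#'
#' @param rx Measurement time series.
#' @param baseline Baseline time series, same length.
#' @return `rx - baseline`.
#' @export
subtract_baseline <- function(rx, baseline) {
  if (length(rx) != length(baseline))
    stop("baseline length does not match record", call. = FALSE)
  rx - baseline
}

#' Transfer-function correction: voltage to moment
#'
#' Divides the one-sided Fourier transform of the receive voltage by the
#' transfer function, rebuilds the conjugate-symmetric spectrum, and inverse
#' transforms, yielding the real-valued magnetic moment (Am^2) -- not its
#' time derivative. Bins where the transfer function is invalid (DC, where
#' Faraday detection has no response) are zeroed; an occupied bin with zero
#' transfer function is an error.
#'
#' @param voltage Receive-voltage time series (V).
#' @param tf A [transfer_function()].
#' @param sampling_rate Samples per second.
#' @return Moment time series (Am^2) with attribute `tf_corrected = TRUE`.
#' @export
tf_correct <- function(voltage, tf, sampling_rate) {
  if (isTRUE(attr(voltage, "tf_corrected")))
    warning("series is already transfer-function corrected")
  n <- length(voltage)
  n2 <- n %/% 2
  freqs <- .bin_freqs(n, sampling_rate)
  tfv <- tf_eval(tf, freqs)
  X <- stats::fft(voltage)[1:(n2 + 1)]
  dead <- Mod(tfv) < 1e-12 * max(Mod(tfv))
  dead[1] <- TRUE  # DC unrecoverable under inductive detection
  occupied <- Mod(X) > 1e-8 * max(Mod(X))
  if (any(dead & occupied & freqs > 0))
    stop("transfer function is zero on an occupied bin", call. = FALSE)
  M <- X / ifelse(dead, 1, tfv)
  M[dead] <- 0 + 0i
  if (n %% 2 == 0) M[n2 + 1] <- complex(real = Re(M[n2 + 1]), imaginary = 0)
  full <- complex(length.out = n)
  full[1:(n2 + 1)] <- M
  if (n2 >= 2) full[n:(n2 + 2)] <- Conj(M[2:n2])
  out <- Re(stats::fft(full, inverse = TRUE)) / n
  attr(out, "tf_corrected") <- TRUE
  out
}

#' Zero all non-harmonic spectral content
#'
#' Projects a commensurate record onto the subspace spanned by the exact
#' harmonic bins of the fundamental (k = 1..K), zeroing everything else
#' (including DC). Applying it twice equals applying it once.
#'
#' @param x Time series whose length is an integer number of periods.
#' @param period_samples Samples per fundamental period.
#' @param K Highest harmonic kept (default 39, capped at Nyquist).
#' @return Filtered time series.
#' @export
zero_nonharmonics <- function(x, period_samples, K = 39) {
  n <- length(x)
  if (n %% period_samples != 0)
    stop("record length is not an integer number of periods", call. = FALSE)
  P <- n %/% period_samples
  K <- min(K, floor(period_samples / 2))
  X <- stats::fft(x)
  keep <- logical(n)
  bins <- (1:K) * P
  keep[bins + 1] <- TRUE
  keep[n - bins + 1] <- TRUE
  X[!keep] <- 0 + 0i
  out <- Re(stats::fft(X, inverse = TRUE)) / n
  attributes(out) <- attributes(x)
  out
}

#' Integrate the B-field monitor signal
#'
#' The field-monitor coil senses dB/dt; cumulative trapezoidal integration
#' recovers the field up to an integration constant, which is fixed by
#' removing the record mean (the drive field has no DC component over whole
#' periods). A DC offset in the input produces a linear ramp; `detrend`
#' removes a fitted linear trend before the mean is removed.
#'
#' @param bmon Monitor voltage time series (V).
#' @param sample_interval Time step (s).
#' @param calibration Field per integrated unit (mT per V s); the inverse of
#'   the monitor coil gain.
#' @param detrend Remove a linear trend after integration (default FALSE).
#' @return Field time series (mT), zero-mean.
#' @export
integrate_bmon <- function(bmon, sample_interval, calibration = 1 / BMON_GAIN,
                           detrend = FALSE) {
  h <- calibration * as.numeric(pracma::cumtrapz(as.numeric(bmon))) * sample_interval
  if (detrend) {
    idx <- seq_along(h)
    h <- stats::lm.fit(cbind(1, idx), h)$residuals
  }
  h - mean(h)
}
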