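#' Per-measurement harmonic time series
#'
#' For each measurement in a run, extracts the complex amplitude at every
#' harmonic k = 1..K via the exact-bin DFT of the receive voltage and
#' converts to magnetic moment by dividing by the transfer function at the
#' harmonic frequency (equivalent to full transfer-function correction
#' restricted to the harmonic bins).
#'
#' @param run An `mps_run` container from [synthesize_in_out_run()] or
#'   [read_run()].
#' @param K Number of harmonics (default 12).
#' @param tf Transfer function; defaults to the one stored with the run.
#' @param baseline Optional voltage time series subtracted from every
#'   measurement before extraction.
#' @return An object of class `harmonic_series`: complex matrix
#'   `amplitudes` (measurements x harmonics, Am^2), `sample_state`,
#'   `index`, and the harmonic frequencies.
#' @export
extract_harmonic_series <- function(run, K = 12, tf = run$tf, baseline = NULL) {
  stopifnot(inherits(run, "mps_run"))
  config <- run$config
  spp <- config$samples_per_period
  n_meas <- length(run$measurements)
  n <- length(run$measurements[[1]]$rx_voltage)
  if (n %% spp != 0)
    stop("record length is not an integer number of drive periods", call. = FALSE)
  if (K > floor(spp / 2)) stop("K exceeds Nyquist", call. = FALSE)
  freqs <- (1:K) * config$drive_frequency
  tfv <- tf_eval(tf, freqs)
  P <- n %/% spp
  bins <- (1:K) * P + 1L
  amps <- matrix(0 + 0i, n_meas, K)
  for (j in seq_len(n_meas)) {
    v <- run$measurements[[j]]$rx_voltage
    if (!is.null(baseline)) v <- subtract_baseline(v, baseline)
    amps[j, ] <- (2 * stats::fft(v)[bins] / n) / tfv
  }
  structure(list(amplitudes = amps,
                 sample_state = vapply(run$measurements, `[[`, character(1),
                                       "sample_state"),
                 index = vapply(run$measurements, `[[`, integer(1), "index"),
                 frequencies = freqs),
            class = "harmonic_series")
}

#' Rolling average within sample-state segments
#'
#' Centered moving mean applied separately inside each contiguous run of
#' identical sample state (so smoothing never crosses an in/out boundary);
#' edge points use shrunken symmetric windows.
#'
#' @param series A `harmonic_series`.
#' @param window Odd window length (default 5).
#' @return A smoothed `harmonic_series`.
#' @export
rolling_average <- function(series, window = 5) {
  stopifnot(inherits(series, "harmonic_series"))
  if (window %% 2 != 1) stop("`window` must be odd", call. = FALSE)
  half <- (window - 1) %/% 2
  st <- series$sample_state
  seg <- cumsum(c(TRUE, st[-1] != st[-length(st)]))
  out <- series$amplitudes
  if (any(tabulate(seg) < window))
    warning("segment shorter than window; smoothed with shrunken windows")
  for (s in unique(seg)) {
    rows <- which(seg == s)
    for (ii in seq_along(rows)) {
      k <- min(half, ii - 1, length(rows) - ii)
      idx <- rows[(ii - k):(ii + k)]
      out[rows[ii], ] <- colMeans(series$amplitudes[idx, , drop = FALSE])
    }
  }
  series$amplitudes <- out
  series
}

#' Linear drift model from sample-out anchors
#'
#' For each harmonic, a complex line through the mean of the first five and
#' the mean of the last five sample-out measurements (mean index vs mean
#' complex amplitude). Evaluating it at every measurement index
#' approximates the expected baseline drift.
#'
#' @param series A `harmonic_series` with at least 5 sample-out measurements
#'   at each end.
#' @param n_anchor Measurements per anchor (default 5).
#' @return An object of class `drift_fit` with complex `intercept` and
#'   `slope` per harmonic.
#' @export
fit_drift_model <- function(series, n_anchor = 5) {
  stopifnot(inherits(series, "harmonic_series"))
  out_idx <- which(series$sample_state == "out")
  if (length(out_idx) < 2 * n_anchor)
    stop("need at least ", 2 * n_anchor, " sample-out measurements", call. = FALSE)
  first <- out_idx[seq_len(n_anchor)]
  last <- out_idx[seq(length(out_idx) - n_anchor + 1, length(out_idx))]
  x1 <- mean(series$index[first]); x2 <- mean(series$index[last])
  y1 <- colMeans(series$amplitudes[first, , drop = FALSE])
  y2 <- colMeans(series$amplitudes[last, , drop = FALSE])
  slope <- (y2 - y1) / (x2 - x1)
  structure(list(intercept = y1 - slope * x1, slope = slope),
            class = "drift_fit")
}

#' Subtract a fitted drift model from a harmonic series
#'
#' @param series A `harmonic_series`.
#' @param drift A `drift_fit` from [fit_drift_model()].
#' @return The drift-corrected `harmonic_series`.
#' @export
remove_drift <- function(series, drift = fit_drift_model(series)) {
  stopifnot(inherits(series, "harmonic_series"), inherits(drift, "drift_fit"))
  pred <- outer(series$index, drift$slope) +
    matrix(drift$intercept, length(series$index), ncol(series$amplitudes),
           byrow = TRUE)
  series$amplitudes <- series$amplitudes - pred
  series
}

#' General linear model for in/out signal amplitude
#'
#' Per harmonic, regresses the complex amplitude time series on a constant,
#' a linear trend in measurement index, and the binary sample-in/out
#' regressor; the in/out coefficient is the signal amplitude. Real and
#' imaginary parts share the design matrix. The noise level is the standard
#' deviation of the sample-out residuals (per component, pooled over real
#' and imaginary parts), and SNR = |amplitude| / residual_sd.
#'
#' @param series A `harmonic_series` (typically after [remove_drift()]).
#' @return An object of class `glm_result` with per-harmonic complex
#'   `signal_amplitude`, `constant`, `trend`, `residual_sd`, `amp_se`
#'   (standard error of each amplitude component), and `snr`.
#' @export
fit_glm <- function(series) {
  stopifnot(inherits(series, "harmonic_series"))
  y <- series$amplitudes
  idx <- series$index
  inout <- as.numeric(series$sample_state == "in")
  X <- cbind(constant = 1, trend = idx - mean(idx), inout = inout)
  if (qr(X)$rank < 3) stop("design matrix is rank deficient", call. = FALSE)
  fit_re <- stats::lm.fit(X, Re(y))
  fit_im <- stats::lm.fit(X, Im(y))
  cf <- matrix(fit_re$coefficients + 1i * fit_im$coefficients,
               nrow = ncol(X), dimnames = list(colnames(X), NULL))
  res <- matrix(fit_re$residuals + 1i * fit_im$residuals, nrow = nrow(y))
  out_rows <- series$sample_state == "out"
  n_out <- sum(out_rows)
  dof <- max(2 * n_out - 2 * ncol(X), 1)
  residual_sd <- sqrt(colSums(Mod(res[out_rows, , drop = FALSE])^2) / dof)
  cjj <- solve(crossprod(X))["inout", "inout"]
  amp <- cf["inout", ]
  structure(list(signal_amplitude = amp,
                 constant = cf["constant", ],
                 trend = cf["trend", ],
                 residual_sd = residual_sd,
                 amp_se = residual_sd * sqrt(cjj),
                 snr = Mod(amp) / residual_sd,
                 dof = dof,
                 frequencies = series$frequencies),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat("In/out GLM amplitudes:\n")
  df <- data.frame(harmonic = seq_along(x$signal_amplitude),
                   amplitude = Mod(x$signal_amplitude),
                   residual_sd = x$residual_sd, snr = x$snr)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Full in/out spectroscopy analysis
#'
#' Convenience pipeline: harmonic extraction, optional rolling average,
#' drift-model removal, and GLM fit.
#'
#' @param run An `mps_run` container.
#' @param K Number of harmonics.
#' @param smooth Apply the five-point rolling average before the GLM
#'   (default FALSE; the GLM handles the unsmoothed series).
#' @return A `glm_result`.
#' @export
analyze_spectroscopy <- function(run, K = 12, smooth = FALSE) {
  hs <- extract_harmonic_series(run, K = K)
  if (smooth) hs <- rolling_average(hs)
  fit_glm(remove_drift(hs))
}

#' Dilution-series sensitivity analysis
#'
#' Proportional fit of signal amplitude against iron mass; the noise floor
#' is the mean noise over all dilution points except the two most
#' concentrated (where sample-correlated noise dominates). Detection limits
#' are the masses at which the fitted signal equals 1x and 5x the noise
#' floor.
#'
#' @param masses Iron masses (kg), length >= 3.
#' @param amplitudes Recovered signal amplitudes (Am^2, magnitudes), one per
#'   mass.
#' @param noise_sds Per-point noise levels (Am^2), one per mass.
#' @return List with `slope` (Am^2 per kg), `noise_floor` (Am^2),
#'   `mass_at_snr1`, `mass_at_snr5` (kg), and `detectable` flag.
#' @export
dilution_sensitivity <- function(masses, amplitudes, noise_sds) {
  if (length(masses) < 3) stop("need at least 3 dilution points", call. = FALSE)
  if (length(amplitudes) != length(masses) || length(noise_sds) != length(masses))
    stop("input lengths differ", call. = FALSE)
  slope <- sum(masses * amplitudes) / sum(masses^2)
  keep <- rank(-masses, ties.method = "first") > 2
  noise_floor <- mean(noise_sds[keep])
  if (!is.finite(slope) || slope <= 0) {
    warning("non-positive sensitivity slope; no detection limit reported")
    return(list(slope = slope, noise_floor = noise_floor,
                mass_at_snr1 = NA_real_, mass_at_snr5 = NA_real_,
                detectable = FALSE))
  }
  list(slope = slope, noise_floor = noise_floor,
       mass_at_snr1 = noise_floor / slope,
       mass_at_snr5 = 5 * noise_floor / slope,
       detectable = TRUE)
}
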