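# Periodic Hann window of length n
.hann <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

# Phase-unwrap a vector (radians)
.unwrap <- function(p) {
  d <- diff(p)
  adj <- cumsum(c(0, -2 * pi * round(d / (2 * pi))))
  p + adj
}

#' Time-resolved harmonic amplitudes (spectrogram lines)
#'
#' Short-time Fourier transform with a periodic Hann window of
#' `window_periods` drive periods and 50 percent overlap, returning the
#' complex line at each requested harmonic of the drive frequency.
#' Amplitudes are normalized so a stationary unit-amplitude cosine reports
#' 1. With 50 percent overlap the hop is an integer number of drive
#' periods, so phase is consistent across frames.
#'
#' @param x Time series (typically a transfer-function-corrected moment).
#' @param period_samples Samples per drive period.
#' @param harmonics Harmonic orders to extract (default 1).
#' @param window_periods Window length in drive periods (default 4).
#' @param overlap Fractional window overlap (default 0.5).
#' @return An object of class `spectro_lines`: complex `lines` matrix
#'   (frames x harmonics) and fractional sample-index `centers`.
#' @export
spectrogram_lines <- function(x, period_samples, harmonics = 1,
                              window_periods = 4, overlap = 0.5) {
  n <- length(x)
  N <- window_periods * period_samples
  if (N > n) stop("window longer than record", call. = FALSE)
  if (max(harmonics) * window_periods >= N / 2)
    stop("harmonic exceeds window Nyquist", call. = FALSE)
  hop <- round(N * (1 - overlap))
  starts <- seq(1L, n - N + 1L, by = hop)
  w <- .hann(N)
  frames <- matrix(x[outer(0:(N - 1), starts, `+`)], nrow = N) * w
  FT <- stats::mvfft(frames)
  bins <- harmonics * window_periods + 1L
  lines <- t(FT[bins, , drop = FALSE]) * (2 / sum(w))
  structure(list(lines = lines, centers = starts + (N - 1) / 2,
                 harmonics = harmonics, window = N, hop = hop),
            class = "spectro_lines")
}

# Crop and fold spectrogram frames over bias periods; returns folded complex
# matrix (phase-bins x harmonics) and the folded bias field per phase-bin.
.fold_over_bias <- function(lines, bias, spb, discard_bias_periods) {
  centers <- lines$centers
  hop <- lines$hop
  if (spb %% hop != 0)
    stop("bias period is not an integer number of STFT hops", call. = FALSE)
  frames_per_bias <- spb %/% hop
  t0 <- discard_bias_periods * spb
  keep <- which(centers > t0)
  n_periods <- length(keep) %/% frames_per_bias
  if (n_periods < 2) stop("fewer than 2 complete bias periods remain", call. = FALSE)
  keep <- keep[seq_len(n_periods * frames_per_bias)]
  L <- lines$lines[keep, , drop = FALSE]
  b <- bias[round(centers[keep])]
  fold_idx <- rep(seq_len(frames_per_bias), n_periods)
  nh <- ncol(L)
  folded <- matrix(0 + 0i, frames_per_bias, nh)
  for (k in seq_len(nh))
    folded[, k] <- tapply(L[, k], fold_idx, mean)
  bias_fold <- as.numeric(tapply(b, fold_idx, mean))
  list(folded = folded, bias = bias_fold, n_periods = n_periods)
}

# Average the up- and down-sweep halves of a folded bias cycle onto the
# up-sweep bias grid (columns of `folded` handled jointly).
.average_halves <- function(folded, bias) {
  nb <- length(bias)
  d <- diff(c(bias, bias[1]))
  up <- d >= 0
  merge_half <- function(idx) {
    o <- order(bias[idx])
    list(b = bias[idx][o], v = folded[idx, , drop = FALSE][o, , drop = FALSE])
  }
  u <- merge_half(which(up)); dn <- merge_half(which(!up))
  if (length(dn$b) < 2) return(list(bias = u$b, values = u$v))
  vi <- matrix(0 + 0i, length(u$b), ncol(folded))
  for (k in seq_len(ncol(folded))) {
    re <- stats::approx(dn$b, Re(dn$v[, k]), xout = u$b, rule = 2)$y
    im <- stats::approx(dn$b, Im(dn$v[, k]), xout = u$b, rule = 2)$y
    vi[, k] <- complex(real = re, imaginary = im)
  }
  list(bias = u$b, values = (u$v + vi) / 2)
}

#' Susceptibility versus bias field
#'
#' The magnetometry-mode reduction: the drive-frequency spectrogram line of
#' the moment, cropped of its first bias periods (start-up), folded and
#' averaged over complete bias periods, divided by the drive amplitude, and
#' paired with the bias field. Up and down bias half-cycles are averaged by
#' default.
#'
#' @param lines A `spectro_lines` with harmonic 1 present.
#' @param bias Bias field time series (mT), same record as the STFT input.
#' @param config An [acq_config()] (for the bias period and drive amplitude).
#' @param discard_bias_periods Start-up bias periods discarded (default 10).
#' @param average_halves Average up/down half-cycles (default TRUE);
#'   `FALSE` keeps the full folded cycle, exposing quasistatic hysteresis.
#' @return An object of class `suscept_curve`: `bias_field` (mT, ordered
#'   when halves are averaged), complex `susceptibility` (Am^2/mT).
#' @export
susceptibility_vs_bias <- function(lines, bias, config,
                                   discard_bias_periods = 10,
                                   average_halves = TRUE) {
  stopifnot(inherits(lines, "spectro_lines"), inherits(config, "acq_config"))
  hcol <- match(1, lines$harmonics)
  if (is.na(hcol)) stop("fundamental line not present", call. = FALSE)
  fl <- .fold_over_bias(lines, bias, config$samples_per_bias_period,
                        discard_bias_periods)
  chi <- fl$folded[, hcol] / config$drive_amplitude
  if (average_halves) {
    av <- .average_halves(cbind(chi), fl$bias)
    out <- list(bias_field = av$bias, susceptibility = av$values[, 1])
  } else {
    out <- list(bias_field = fl$bias, susceptibility = chi)
  }
  structure(c(out, list(drive_amplitude = config$drive_amplitude,
                        n_periods = fl$n_periods,
                        averaged_halves = average_halves)),
            class = "suscept_curve")
}

#' @export
print.suscept_curve <- function(x, ...) {
  cat(sprintf("Susceptibility curve: %d bias points over [%0.3g, %0.3g] mT, %d bias periods averaged\n",
              length(x$bias_field), min(x$bias_field), max(x$bias_field),
              x$n_periods))
  invisible(x)
}

#' @export
plot.suscept_curve <- function(x, ...) {
  graphics::plot(x$bias_field, Mod(x$susceptibility), type = "l",
                 xlab = "Bias field (mT)", ylab = "|Susceptibility| (Am^2/mT)", ...)
  invisible(x)
}

#' Integrate a susceptibility curve to the quasistatic magnetization curve
#'
#' Cumulative trapezoidal integration of the in-phase susceptibility over
#' the bias field, with the boundary condition that the mean magnetization
#' over the swept range is zero.
#'
#' @param curve A `suscept_curve` on an ordered bias grid.
#' @return A data.frame with `bias_field` (mT) and `moment` (Am^2).
#' @export
integrate_susceptibility <- function(curve) {
  stopifnot(inherits(curve, "suscept_curve"))
  h <- curve$bias_field
  if (is.unsorted(h)) stop("bias grid must be ordered; use averaged halves",
                           call. = FALSE)
  m <- as.numeric(pracma::cumtrapz(h, Re(curve$susceptibility)))
  data.frame(bias_field = h, moment = m - mean(m))
}

#' Full width at half maximum of a susceptibility curve
#'
#' Linear-interpolated width of |chi| at half its peak. The curve must be
#' unimodal: exactly one rising and one falling half-maximum crossing.
#'
#' @param curve A `suscept_curve` (or any list with `bias_field` and
#'   `susceptibility`).
#' @return FWHM (mT).
#' @export
fwhm <- function(curve) {
  h <- curve$bias_field
  y <- Mod(curve$susceptibility)
  half <- max(y) / 2
  above <- y >= half
  runs <- rle(above)
  if (sum(runs$values) != 1)
    stop(sprintf("curve is not unimodal at half maximum (%d disjoint regions above half peak)",
                 sum(runs$values)), call. = FALSE)
  i1 <- which(above)[1]
  i2 <- max(which(above))
  left <- if (i1 == 1) h[1] else {
    stats::approx(y[(i1 - 1):i1], h[(i1 - 1):i1], xout = half)$y
  }
  right <- if (i2 == length(y)) h[length(h)] else {
    stats::approx(y[i2:(i2 + 1)], h[i2:(i2 + 1)], xout = half)$y
  }
  right - left
}

#' Fit a Langevin curve to quasistatic magnetization data
#'
#' Least-squares fit of m(H) = a * L(b * H) with the scale solved linearly
#' at each steepness, used to recover beta from an integrated
#' susceptibility curve.
#'
#' @param bias_field Field samples (mT).
#' @param moment Moment samples (Am^2).
#' @param beta_init Initial steepness (1/mT, default 1).
#' @return List with `msat` (Am^2) and `beta` (1/mT).
#' @export
fit_langevin_curve <- function(bias_field, moment, beta_init = 1) {
  sse <- function(lb) {
    s <- langevin(exp(lb) * bias_field)
    a <- sum(moment * s) / sum(s^2)
    sum((moment - a * s)^2)
  }
  opt <- stats::optimize(sse, log(beta_init) + c(-5, 5), tol = 1e-10)
  beta <- exp(opt$minimum)
  s <- langevin(beta * bias_field)
  list(msat = sum(moment * s) / sum(s^2), beta = beta)
}

#' One-dimensional system matrix
#'
#' Extends the magnetometry reduction to all harmonics 1..K: per-harmonic
#' complex spectrogram lines folded and averaged over bias periods, mapping
#' bias field (emulating position in the imaging gradient) to harmonic
#' response. Provides magnitude and bias-axis phase-unwrapped views.
#'
#' @param x Moment time series (after preprocessing).
#' @param bias Bias field time series (mT).
#' @param config An [acq_config()].
#' @param K Number of harmonics (default 39).
#' @param discard_bias_periods Start-up bias periods discarded (default 10).
#' @param window_periods STFT window length in drive periods (default 4).
#' @param average_halves Average up/down half-cycles (default TRUE).
#' @return An object of class `system_matrix_1d`: `bias_field`, complex
#'   `matrix` (bias points x K), `magnitude`, `phase` (unwrapped along bias).
#' @export
system_matrix <- function(x, bias, config, K = 39, discard_bias_periods = 10,
                          window_periods = 4, average_halves = TRUE) {
  stopifnot(inherits(config, "acq_config"))
  lines <- spectrogram_lines(x, config$samples_per_period, harmonics = 1:K,
                             window_periods = window_periods)
  fl <- .fold_over_bias(lines, bias, config$samples_per_bias_period,
                        discard_bias_periods)
  if (average_halves) {
    av <- .average_halves(fl$folded, fl$bias)
    b <- av$bias; M <- av$values
  } else {
    b <- fl$bias; M <- fl$folded
  }
  phase <- apply(Arg(M), 2, .unwrap)
  structure(list(bias_field = b, matrix = M, magnitude = Mod(M),
                 phase = phase, harmonics = 1:K, n_periods = fl$n_periods),
            class = "system_matrix_1d")
}

#' @export
print.system_matrix_1d <- function(x, ...) {
  cat(sprintf("1-D system matrix: %d bias points x %d harmonics (%d bias periods averaged)\n",
              length(x$bias_field), length(x$harmonics), x$n_periods))
  invisible(x)
}

#' @export
plot.system_matrix_1d <- function(x, harmonics = 1:min(9, length(x$harmonics)), ...) {
  old <- graphics::par(mfrow = c(ceiling(length(harmonics) / 3), 3),
                       mar = c(2.5, 2.5, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (k in harmonics) {
    graphics::plot(x$bias_field, x$magnitude[, k], type = "l",
                   xlab = "", ylab = "", main = paste0("h", k), ...)
  }
  invisible(x)
}

#' Magnetometry-mode analysis of a biased run
#'
#' Transfer-function-corrects the receive voltage, extracts the
#' drive-frequency spectrogram line, folds it against the bias field, and
#' integrates to the quasistatic magnetization curve.
#'
#' @param run An `mps_run` from [synthesize_biased_run()].
#' @param discard_bias_periods Start-up bias periods discarded (default 10).
#' @param window_periods STFT window length in drive periods (default 4).
#' @return List with the `suscept_curve`, the magnetization `curve`
#'   data.frame, the `fwhm_mT`, and the Langevin fit of the curve.
#' @export
analyze_magnetometry <- function(run, discard_bias_periods = 10,
                                 window_periods = 4) {
  stopifnot(inherits(run, "mps_run"))
  config <- run$config
  v <- run$measurements[[1]]$rx_voltage
  if (!is.null(run$baseline)) v <- subtract_baseline(v, run$baseline)
  m_est <- tf_correct(v, run$tf, config$sampling_rate)
  lines <- spectrogram_lines(m_est, config$samples_per_period, harmonics = 1,
                             window_periods = window_periods)
  sc <- susceptibility_vs_bias(lines, run$channels$bias_monitor, config,
                               discard_bias_periods = discard_bias_periods)
  mc <- integrate_susceptibility(sc)
  lf <- fit_langevin_curve(mc$bias_field, mc$moment,
                           beta_init = if (!is.null(run$particle))
                             run$particle$beta else 1)
  list(susceptibility = sc, curve = mc, fwhm_mT = fwhm(sc), langevin_fit = lf)
}

#' System-matrix analysis of a biased run
#'
#' @param run An `mps_run` from [synthesize_biased_run()] at imaging drive
#'   amplitude.
#' @param K Number of harmonics (default 39).
#' @param discard_bias_periods Start-up bias periods discarded (default 10).
#' @return A `system_matrix_1d`.
#' @export
analyze_system_matrix <- function(run, K = 39, discard_bias_periods = 10) {
  stopifnot(inherits(run, "mps_run"))
  config <- run$config
  v <- run$measurements[[1]]$rx_voltage
  if (!is.null(run$baseline)) v <- subtract_baseline(v, run$baseline)
  m_est <- tf_correct(v, run$tf, config$sampling_rate)
  system_matrix(m_est, run$channels$bias_monitor, config, K = K,
                discard_bias_periods = discard_bias_periods)
}
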