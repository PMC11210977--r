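#' Langevin function
#'
#' L(x) = coth(x) - 1/x, the equilibrium magnetization law for an ensemble of
#' superparamagnetic moments. Odd, bounded in (-1, 1), with a removable
#' singularity at 0 handled by the series x/3 - x^3/45 for |x| < 1e-4.
#'
#' @param x Numeric vector (dimensionless field argument, typically beta * H).
#' @return L(x), same shape as `x`.
#' @examples
#' langevin(0)    # 0
#' langevin(1)    # coth(1) - 1 = 0.3130...
#' @export
langevin <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`x` must be finite numeric", call. = FALSE)
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 45
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  dim(out) <- dim(x)
  out
}

#' Derivative of the Langevin function
#'
#' L'(x) = 1/x^2 - 1/sinh(x)^2, with series 1/3 - x^2/15 near zero. The
#' small-field susceptibility shape used by the magnetometry oracle.
#'
#' @param x Numeric vector.
#' @return L'(x).
#' @export
langevin_deriv <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-3
  xs <- x[small]
  out[small] <- 1 / 3 - xs^2 / 15
  xl <- x[!small]
  out[!small] <- 1 / xl^2 - 1 / sinh(xl)^2
  dim(out) <- dim(x)
  out
}

#' Nanoparticle model
#'
#' Saturation moment, Langevin steepness, and relaxation kernel of a
#' superparamagnetic sample. `beta` multiplies the applied field expressed in
#' mT (i.e. it is quoted against mu0*H), matching how instrument fields are
#' specified. The kernel families are `"none"` (adiabatic), `"debye"` (single
#' effective time constant) and `"two_pole"` (normalized biexponential
#' difference).
#'
#' @param saturation_moment Total sample saturation moment M_sat (Am^2), >= 0.
#' @param beta Langevin steepness (1/mT), > 0.
#' @param kernel One of `"none"`, `"debye"`, `"two_pole"`.
#' @param tau_eff Effective relaxation time constant (s), for `"debye"`.
#' @param tau1,tau2 Time constants (s) for `"two_pole"`; must differ.
#' @return An object of class `particle_model`.
#' @examples
#' particle_model(1e-7, beta = 1, kernel = "debye", tau_eff = 3e-6)
#' @export
particle_model <- function(saturation_moment, beta,
                           kernel = c("none", "debye", "two_pole"),
                           tau_eff = NULL, tau1 = NULL, tau2 = NULL) {
  kernel <- match.arg(kernel)
  .check_nonneg(saturation_moment, "saturation_moment")
  .check_pos(beta, "beta")
  if (kernel == "debye") {
    if (is.null(tau_eff)) stop("`tau_eff` required for debye kernel", call. = FALSE)
    .check_pos(tau_eff, "tau_eff")
  }
  if (kernel == "two_pole") {
    if (is.null(tau1) || is.null(tau2))
      stop("`tau1` and `tau2` required for two_pole kernel", call. = FALSE)
    .check_pos(tau1, "tau1")
    .check_pos(tau2, "tau2")
    if (tau1 == tau2) stop("`tau1` and `tau2` must differ", call. = FALSE)
  }
  structure(list(saturation_moment = saturation_moment, beta = beta,
                 kernel = kernel, tau_eff = tau_eff, tau1 = tau1, tau2 = tau2),
            class = "particle_model")
}

#' @export
print.particle_model <- function(x, ...) {
  cat("Particle model: M_sat =", format(x$saturation_moment), "Am^2, beta =",
      format(x$beta), "1/mT, kernel =", x$kernel, "\n")
  if (x$kernel == "debye") cat("  tau_eff =", format(x$tau_eff * 1e6), "us\n")
  if (x$kernel == "two_pole")
    cat("  tau1 =", format(x$tau1 * 1e6), "us, tau2 =", format(x$tau2 * 1e6), "us\n")
  invisible(x)
}

#' Applied-field waveform on a uniform time grid
#'
#' @param samples Field samples (mT).
#' @param sample_interval Time step (s), > 0.
#' @param period_samples Samples per declared fundamental period; the record
#'   length must be an integer multiple of it.
#' @return An object of class `field_waveform`.
#' @export
field_waveform <- function(samples, sample_interval, period_samples) {
  .check_pos(sample_interval, "sample_interval")
  if (period_samples < 1 || period_samples != round(period_samples))
    stop("`period_samples` must be a positive integer", call. = FALSE)
  n <- length(samples)
  if (n == 0 || n %% period_samples != 0)
    stop("record length must be a positive integer multiple of `period_samples`",
         call. = FALSE)
  structure(list(samples = as.numeric(samples), sample_interval = sample_interval,
                 period_samples = as.integer(period_samples)),
            class = "field_waveform")
}

#' Adiabatic (relaxation-free) magnetization
#'
#' M_ad(t) = M_sat * L(beta * H(t)) evaluated pointwise.
#'
#' @param field A [field_waveform()] (mT).
#' @param particle A [particle_model()].
#' @return Moment waveform (Am^2), numeric vector.
#' @export
adiabatic_magnetization <- function(field, particle) {
  stopifnot(inherits(field, "field_waveform"), inherits(particle, "particle_model"))
  particle$saturation_moment * langevin(particle$beta * field$samples)
}

#' Discrete relaxation kernel
#'
#' Samples the causal relaxation kernel on the given time grid and
#' renormalizes so that sum(kernel) * dt = 1 (unit DC gain after
#' discretization). Debye: (1/tau) exp(-t/tau). Two-pole: the normalized
#' biexponential difference (exp(-t/tau1) - exp(-t/tau2)) / (tau1 - tau2).
#'
#' @param particle A [particle_model()] with kernel != "none".
#' @param time_grid Vector of times (s), uniform from 0.
#' @return Kernel samples (1/s) summing to `1/dt`.
#' @export
relaxation_kernel <- function(particle, time_grid) {
  stopifnot(inherits(particle, "particle_model"))
  if (particle$kernel == "none")
    stop("particle has no relaxation kernel", call. = FALSE)
  t <- as.numeric(time_grid)
  dt <- t[2] - t[1]
  taus <- switch(particle$kernel,
                 debye = particle$tau_eff,
                 two_pole = c(particle$tau1, particle$tau2))
  if (dt > min(taus) / 5)
    warning("time step exceeds tau/5; kernel discretization is coarse")
  # single-tau kernel, sampled with a trapezoidal weight at the causal edge
  # (removes the half-sample phase bias of left-endpoint quadrature) and
  # renormalized to unit DC gain after discretization
  debye_disc <- function(tau) {
    r <- exp(-t / tau) / tau
    r[1] <- r[1] / 2
    r / (sum(r) * dt)
  }
  r <- switch(particle$kernel,
    debye = debye_disc(particle$tau_eff),
    # biexponential difference as the exact mixture
    # (tau1 * D_tau1 - tau2 * D_tau2) / (tau1 - tau2) of unit-DC kernels:
    # smooth in both poles, with the single-tau kernel as the tau2 -> 0 limit
    two_pole = {
      t1 <- particle$tau1; t2 <- particle$tau2
      (t1 * debye_disc(t1) - t2 * debye_disc(t2)) / (t1 - t2)
    })
  s <- sum(r) * dt
  if (s <= 0) stop("kernel normalization failed", call. = FALSE)
  r / s
}

#' Apply a relaxation kernel in periodic steady state
#'
#' Circular convolution of a periodic waveform with the particle's discrete
#' relaxation kernel, i.e. the steady-state response after start-up
#' transients have decayed. A particle with kernel `"none"` returns the input
#' unchanged.
#'
#' @param x Periodic waveform samples.
#' @param particle A [particle_model()].
#' @param sample_interval Time step (s).
#' @param period_samples Samples per declared fundamental period; the kernel
#'   support (10 * max tau) must not exceed 10 declared periods.
#' @return Convolved waveform, same length as `x`.
#' @export
apply_kernel <- function(x, particle, sample_interval, period_samples = length(x)) {
  stopifnot(inherits(particle, "particle_model"))
  if (particle$kernel == "none") return(x)
  taus <- switch(particle$kernel,
                 debye = particle$tau_eff,
                 two_pole = c(particle$tau1, particle$tau2))
  period_dur <- period_samples * sample_interval
  if (10 * max(taus) > 10 * period_dur)
    stop("kernel support exceeds 10 periods; not a periodic steady-state regime",
         call. = FALSE)
  n <- length(x)
  r <- relaxation_kernel(particle, (seq_len(n) - 1) * sample_interval)
  Re(stats::fft(stats::fft(x) * stats::fft(r), inverse = TRUE)) / n * sample_interval
}

#' Steady-state magnetization response
#'
#' M(t) = (M_ad * r)(t): the adiabatic Langevin magnetization convolved with
#' the particle's relaxation kernel, computed as a circular convolution over
#' the periodic extension of the record (periodic steady state).
#'
#' @param field A [field_waveform()].
#' @param particle A [particle_model()].
#' @return Moment waveform (Am^2).
#' @export
magnetization_response <- function(field, particle) {
  m_ad <- adiabatic_magnetization(field, particle)
  apply_kernel(m_ad, particle, field$sample_interval, field$period_samples)
}

#' Harmonic amplitudes of a periodic waveform
#'
#' Exact-bin discrete Fourier coefficients at multiples of the fundamental,
#' scaled so that a unit-amplitude cosine at k*f0 reports complex amplitude 1.
#' Requires the record to hold an integer number of periods (no leakage).
#'
#' @param x Waveform samples over an integer number of periods.
#' @param period_samples Samples per fundamental period.
#' @param K Highest harmonic returned (default: up to Nyquist).
#' @return Complex vector of length `K`, harmonics 1..K.
#' @export
harmonic_spectrum <- function(x, period_samples, K = NULL) {
  n <- length(x)
  if (n %% period_samples != 0)
    stop("record length is not an integer number of periods", call. = FALSE)
  P <- n %/% period_samples
  kmax <- floor(period_samples / 2)
  if (is.null(K)) K <- kmax
  if (K > kmax)
    stop("requested harmonic exceeds Nyquist", call. = FALSE)
  X <- stats::fft(x)
  2 * X[(1:K) * P + 1] / n
}
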