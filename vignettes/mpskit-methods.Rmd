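---
title: "Models and methods behind mpskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpskit)
```

mpskit emulates, end to end, the computational core of a magnetic particle
spectrometer/relaxometer/loop tracer: the nanoparticle physics, the
instrument signal chain, and the five analysis modes. This vignette is the
package's own account of the models, the numerical choices, and what the
synthetic tests do and do not demonstrate about real hardware.

## Particle model

The equilibrium magnetization of a superparamagnetic ensemble follows the
Langevin law $M_\mathrm{ad}(t) = M_\mathrm{sat} L(\beta H(t))$ with
$L(x)=\coth x - 1/x$. Two conventions matter:

* **$\beta$ is quoted against the field in mT** (i.e. against $\mu_0 H$),
  because every instrument field — drive amplitude, bias amplitude — is
  specified in mT. Physically $\beta = \mu m / (k_B T)$ per unit mT for a
  particle of moment $m$; for MPI tracers $\beta$ is of order 0.1–1 mT$^{-1}$.
* **The removable singularity at $x=0$** is handled by the odd series
  $x/3 - x^3/45$ for $|x|<10^{-4}$; beyond that the direct form is exact to
  machine precision (the series/direct crossover agrees to $\sim10^{-8}$,
  limited by cancellation in $\coth x - 1/x$ at small $x$).

Relaxation enters as convolution with a causal kernel of unit DC gain: the
single-time-constant (Debye) kernel
$r(t)=\tau_\mathrm{eff}^{-1}e^{-t/\tau_\mathrm{eff}}u(t)$, or a two-pole
kernel. The two-pole form is implemented as the normalized biexponential
difference $(e^{-t/\tau_1}-e^{-t/\tau_2})/(\tau_1-\tau_2)$: the raw
difference of two rate-normalized exponentials integrates to zero and
cannot be a magnetization kernel, so the unit-DC normalization is the only
physically meaningful reading. Discretely the two-pole kernel is built as
the exact mixture $(\tau_1 D_{\tau_1}-\tau_2 D_{\tau_2})/(\tau_1-\tau_2)$
of two discretized unit-DC single-$\tau$ kernels, which is smooth in both
poles and reduces exactly to the single-$\tau$ kernel as $\tau_2\to 0$ —
the limit that degenerate fits approach.

### Kernel discretization

Kernels are sampled on the record's grid and renormalized so that
$\sum_j r_j\,\Delta t = 1$, preserving DC gain exactly at any step size.
The causal-edge sample is halved (trapezoidal quadrature weight): plain
left-endpoint sampling of the convolution integral carries a first-order
half-sample phase bias ($\omega\Delta t/2$, about 37 mrad at 23.8 kHz and
2 MHz sampling) which the trapezoidal edge removes. With the kernel
resolved ($\Delta t/\tau \lesssim 0.02$) and $\omega\Delta t \lesssim 0.03$,
the discrete response matches the analytic Debye response
$1/(1+i\omega\tau)$ to better than $10^{-4}$ across
$\omega\tau \in [0.01, 10]$; a warning is raised when
$\Delta t > \tau/5$. Steady state is computed by circular convolution over
the declared period — the periodic fixed point the hardware reaches after
its discarded start-up periods — rather than by transient simulation.

## Instrument emulation

The timing contract is the device's: 2 MHz sampling, 42 µs drive period
(84 samples, exactly), 84 ms bias period (exactly 2000 drive periods).
Commensurability is enforced at configuration time so every drive period
is sample-identical and harmonic bins are leakage-free.

The receive chain maps moment to voltage through a complex transfer
function. The default is parametric — flat gain × ideal Faraday
differentiator $i2\pi f$ × second-order notch at the drive frequency with
30 dB depth ($Q=2$) — capturing the structure that matters to the
pipeline: no DC response, a deliberately suppressed fundamental, and
smooth growth across the harmonics. A measured transfer function from a
calibration sweep (15-turn, 5 mm test coil; $TF = V/(N I A)$ at exact
bins) drops in identically. Because synthesis and correction evaluate the
same grid-interpolated object, the round trip is exact to $10^{-13}$;
real calibrations instead contribute their own error, which is why the
measured-TF path is exercised with noisy sweeps in the tests.

Non-idealities are generated at the levels the design budgets anticipate:

* **Feedthrough**: an equivalent drive moment at $f_0$ (default
  $7.5\times10^{-5}$ Am², i.e. 250 A-turns × $3\times10^{-4}$ m² × a
  −60 dB gradiometer) plus a third-harmonic component at a configurable
  dBc (default −108 dBc).
* **Drift**: per-measurement complex scaling of the moment contribution,
  0.1 % amplitude and 1 mrad phase per 100 measurements by default.
  Drift is per-measurement (not intra-measurement) because that is the
  granularity at which the stability budget is specified.
* **Noise**: white Gaussian voltage noise of configurable density at the
  output; $10^{-7}$ V/√Hz is used as the realistic default in the
  acceptance runs, which puts the single-measurement harmonic-bin SNR of
  a ~0.5 µg-equivalent sample in the $10^3$–$10^4$ range, comparable to a
  healthy benchtop chain.
* **Seeding**: one master seed per run; each measurement's noise stream is
  seeded as master + index, so whole runs and individual measurements
  reproduce bit-for-bit. Containers carry no wall-clock fields, so equal
  seeds give byte-identical files.

The monitor channels are ideal: the B-monitor is an exact scaled $dB/dt$
of the applied field and the drive-current monitor an exact scaled drive
current. Eddy-current phase shifts between field and current, amplifier
nonlinearity, multiplexing ghosts, and quantization are not modeled (a
16-bit toggle was considered and left out as orthogonal to the analysis
path).

## Spectroscopy statistics

A run is the schedule 11 out / 11 in / 11 out / 11 in / 11 out — the
in/out cycle "repeated 2.5 times", read so the run begins and ends
sample-out, which is exactly what the drift model needs for its anchors.
Per measurement and harmonic, the complex amplitude comes from the
exact-bin DFT divided by the transfer function at that bin (equivalent to
full correction restricted to harmonic bins, and cheaper).

The drift model is a complex line through the means of the first five and
last five sample-out measurements, evaluated at every index and
subtracted. The remaining series feeds a general linear model with
constant, linear-trend, and in/out-boxcar regressors; real and imaginary
parts share the design matrix and are solved jointly as stacked
least-squares (equivalent to independent component fits with a single
residual definition). The five-point rolling average is applied within
state segments only — smoothing across an in/out boundary would bias the
boxcar — and is off by default on the GLM path, which needs no smoothing.

The noise level is the sample-out residual standard deviation per
component, pooled over real and imaginary parts with
$2(n_\mathrm{out}-p)$ degrees of freedom, and SNR
$=|a|/\sigma$. For detection, the per-component statistic
$z = \mathrm{Re}(a)/\mathrm{se}(a)$ (and likewise imaginary) with
$\mathrm{se}(a)=\sigma\sqrt{[(X'X)^{-1}]_{33}}$ is used: with ~100 pooled
degrees of freedom its two-sided 3σ false-positive rate is ≈0.34 %,
which the acceptance run verifies empirically on 500 zero-mass runs. A
Rayleigh-type test on $|a|$ would have a different null (≈1.1 % at 3σ
per complex amplitude) and is not what a "3σ" detection means here.

Dilution-series sensitivity fits signal $\propto$ mass through the origin
and averages the noise floor over all points except the two most
concentrated (where sample-correlated noise dominates in practice);
detection limits are noise floor (× 5) over slope.

## Relaxometry

Loops are built by folding all drive periods onto one (exact phase
alignment is guaranteed by commensurability) and pairing moment with
field. The fit minimizes the time-domain sum of squared residuals of
$\hat m(t) = s\,[L(\beta H)\ast r](t)$ with the scale $s$ solved linearly
at every objective evaluation, leaving a 2- (Debye) or 3-parameter
(two-pole) Nelder-Mead search in log space. Initial values: $\tau_0 =
1/2\pi f_0$ and $\beta_0$ from the loop's saturation knee (the field
where $|m|$ reaches 80 % of its maximum, inverted through $L$), falling
back to 1 mT$^{-1}$ for non-saturating loops. A deterministic ladder of
3–4 starts (including, for the two-pole model, a near-degenerate
$\tau_2$ start) guards against local minima; ties go to the smaller
$\tau$ sum. $\tau$ is confined to [numerical zero, one drive period]:
beyond a period the periodic steady-state model stops being meaningful.
Fits whose $\tau$ collapses below $\Delta t/10$ are reported at that
floor with a `tau_floored` flag rather than silently clamped —
single-$\tau$ data pulled through the two-pole model routinely produce
such degenerate second poles.

## Quasistatic modes

The magnetometry mode probes with a weak drive (1 mT default) while the
bias sweeps ±50 mT at 11.9 Hz. The short-time Fourier transform uses a
periodic Hann window of 4 drive periods and 50 % overlap — the overlap is
a choice (unstated in the source procedure); 50 % makes the hop an
integer number of drive periods, so every frame is phase-coherent, and
Hann at 50 % satisfies constant overlap-add. Amplitudes are normalized so
a stationary unit cosine reports 1 (exact at integer bins). Frames from
the first 10 bias periods are discarded by default (the hardware's
start-up allowance; the simulator's circular steady state makes this a
procedural no-op), the rest folded over the bias period and averaged,
then the up and down half-cycles averaged onto a common monotone grid
(a flag preserves them separately to expose quasistatic hysteresis). The
bias axis comes from the bias-current channel, mirroring the instrument.

The susceptibility is the folded drive-frequency line divided by the
drive amplitude; its cumulative-trapezoid integral with the zero-mean
boundary condition is the quasistatic m(H). For a Langevin particle
$\chi(H)=M_\mathrm{sat}\beta L'(\beta H)$, and the closure test recovers
$M_\mathrm{sat}L(\beta H)$ within 2 % of $M_\mathrm{sat}$ and $\beta$
within 2 % at the default noise — *provided the probe is linear*:
$\beta A_\mathrm{drive} \le 0.3$ (the configuration warns beyond that).
Finite probe amplitude smooths $\chi$ like a kernel of width
$A_\mathrm{drive}$, which at $\beta A = 1$ already distorts the peak by
~3 %.

The 1-D system matrix is the same pipeline retaining harmonics 1..39.
Two resolution limits are inherent to the windowed measurement and are
worth stating precisely because they bound any agreement with a
frozen-bias (static) oracle:

* within one 4-period window the bias moves by up to
  $2\pi \cdot 4/2000 \cdot 50\ \mathrm{mT} \approx 0.63$ mT near its zero
  crossing, blurring harmonic structure on that scale;
* Hann sidelobes leak a few times $10^{-3}$ of the neighboring harmonics
  (4 window-bins away) into each line, which matters where an even
  harmonic's small row sits next to an odd harmonic ~100× larger.

For a hard-saturating particle ($\beta = 1$ mT$^{-1}$, 10 mT drive) the
static-bias oracle therefore agrees to 3 % of each row's peak only up to
harmonic ~19; above that the deviation grows roughly linearly in the
harmonic index (tens of percent by k≈38 near zero bias). This is a
property of the measurement definition, not of the implementation — the
symmetry structure (odd harmonics even in bias, even harmonics odd and
vanishing at zero bias) holds across all 39 harmonics. The acceptance
checks assert the 3 % oracle bound over k = 1..19 and report the
full-range deviation alongside.

## Problem sizes and tolerances used

The test and acceptance runs choose sizes that keep each property in its
asymptotic regime: Debye fidelity on $2^{17}$-sample records with the
kernel resolved as above; relaxation recovery on single folded periods
(84 points) over the $\tau \in \{0.5,1,2.5,5\}$ µs × $\beta \in
\{0.5,1,2\}$ mT$^{-1}$ grid, noiseless to 1 % and at loop-SNR 100 to
10 % over 20 seeds; the GLM null on 500 spectroscopy runs of 55 × 10
drive periods; magnetometry on 24 bias periods (≈2 s of signal) at the
instrument's native factor-2000 timing; the system matrix on 6 bias
periods. BMon integration is trapezoid-limited: at 84 samples per period
its error bound is $(\omega\Delta t)^2/12 \approx 4.7\times10^{-4}$
relative, and the tests assert that bound rather than a tighter figure.

## What passing does and does not show

The generator reproduces the *form* of instrument data — timing,
feedthrough, drift, white noise, transfer-function shaping — under
exactly known particles, so green tests certify the analysis chain:
unbiased amplitude recovery, correct null statistics, correct kernel
physics, closure of the quasistatic integral. They do not certify
hardware-determined figures (absolute sensitivity in grams of iron,
measured THD, pAm² noise floors), which depend on coils, amplifiers, and
shielding outside any simulation's reach; nor do they validate the Debye
model itself against real tracer physics (field-dependent time constants,
size distributions, and stochastic dynamics are out of scope). The run
container is a schema-versioned serialized R object with CSV exports for
flat products; its layout (config, particle, transfer function, channel
arrays, states, seed) is documented in `?write_run`.
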