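# mpskit

Desk-scale simulation and analysis for magnetic particle spectroscopy (MPS),
relaxometry, hysteresis loop tracing, quasistatic magnetometry, and 1-D
system-matrix measurement of superparamagnetic iron oxide nanoparticles
(SPIONs) — the tracer-characterization workhorses of magnetic particle
imaging (MPI).

It is written for instrument builders and tracer developers who want to
prototype and validate the *software* side of an MPS/relaxometer — the
signal chain, the harmonic detection statistics, the loop/relaxation fits,
and the spectrogram-based quasistatic modes — against a fully controlled
synthetic instrument, and to budget the hardware with the standard
closed-form design calculations.

## The model

A SPION ensemble in an applied field `H(t)` (mT) magnetizes adiabatically
following the Langevin law

    M_ad(t) = M_sat * L(beta * H(t)),     L(x) = coth(x) - 1/x,

where `M_sat` (Am^2) is the sample's saturation moment and `beta` (1/mT)
the Langevin steepness. Finite relaxation (Neel/Brownian) delays the
response by convolution with a causal kernel,

    M(t) = (M_ad * r)(t),      r(t) = (1/tau_eff) exp(-t/tau_eff) u(t)

for the single-time-constant (Debye) kernel, or the normalized
biexponential difference `(exp(-t/tau1) - exp(-t/tau2)) / (tau1 - tau2)`
for the two-pole kernel. The receive chain is inductive: the voltage is
`V(f) = TF_Rx(f) * M(f)`, with `TF_Rx` a differentiator-times-notch
transfer function (V per Am^2) measured by a calibration coil and divided
out in preprocessing, so analysis works on the magnetic moment itself.

The emulated instrument runs at 2 MHz sampling with a 42 us drive period
(23.8 kHz, 84 samples per period, every period sample-identical) and an
84 ms bias period holding exactly 2000 drive periods. The five analysis
modes are:

- **Spectroscopy** — sample-in/out measurement schedules (11 out, 11 in,
  repeated 2.5 times), per-harmonic amplitudes by exact-bin DFT, a linear
  drift model anchored on the first/last sample-out blocks, and a general
  linear model (constant + trend + in/out boxcar) whose boxcar coefficient
  is the signal amplitude; noise is the sample-out residual sd.
- **Relaxometry** — fold the record into one drive period, then Nelder-Mead
  fit of `(tau, beta, scale)` through the Langevin + kernel forward model.
- **Loop tracing** — moment against the field integrated from the dB/dt
  monitor coil (cumulative trapezoid, zero-mean constant).
- **Magnetometry** — weak drive (1 mT) as a linear probe while a 50 mT bias
  sweeps slowly; the drive-frequency spectrogram line (4-period Hann
  window) against bias is the susceptibility curve chi(H); its integral is
  the quasistatic magnetization curve m(H).
- **1-D system matrix** — same pipeline saving all harmonics 1..39 versus
  bias, the map MPI reconstruction needs.

## Worked example

```r
library(mpskit)

## hardware design budget
rep <- design_report()
sprintf("Feedthrough moment: %.2e Am^2", rep$feedthrough_moment_Am2)
sprintf("Required drive purity: %.1f dBc", rep$purity_dbc)
sprintf("Skin depth at 23.8 kHz: %.2f mm", rep$skin_depth_m * 1e3)

## synthetic in/out spectroscopy run and GLM analysis
cfg      <- acq_config(periods_per_measurement = 500, random_seed = 42)
particle <- particle_model(5.5e-7, beta = 1, kernel = "debye", tau_eff = 2.5e-6)
tf       <- tf_default(cfg)
run      <- synthesize_in_out_run(particle, cfg, tf, noise_density = 1e-8, seed = 42)
analyze_spectroscopy(run, K = 5)

## hysteresis loop and relaxation fit from the same run
drive <- make_drive_waveform(cfg)
m <- tf_correct(subtract_baseline(run$measurements[[12]]$rx_voltage,
                                  run$measurements[[1]]$rx_voltage),
                tf, cfg$sampling_rate)
loop <- build_loop(m, drive$samples, cfg$samples_per_period, drive$sample_interval)
fit_relaxation(loop, model = "debye")
```

Output:

```
[1] "Feedthrough moment: 7.50e-05 Am^2"
[1] "Required drive purity: -106.2 dBc"
[1] "Skin depth at 23.8 kHz: 0.42 mm"
In/out GLM amplitudes:
 harmonic    amplitude  residual_sd          snr
        1 5.581916e-07 2.771523e-11 2.014025e+04
        2 3.594836e-14 2.345008e-13 1.532974e-01
        3 9.316107e-08 3.699809e-12 2.517997e+04
        4 7.965931e-14 1.233810e-13 6.456366e-01
        5 2.698778e-08 1.071079e-12 2.519682e+04
Relaxation fit (debye kernel)
  tau_eff = 2.368 us
  beta = 0.9321 1/mT, M_sat scale = 5.581e-07 Am^2
  SSE = 3.446e-16, converged = TRUE
```

Reading it: odd harmonics carry the particle signal (the Langevin response
to an unbiased sinusoid is odd, so even harmonics sit at the noise floor —
their SNR is below 1); the recovered amplitude at the fundamental matches
the generated `M_sat * L` response, and the relaxation fit recovers the
generating `tau_eff = 2.5 us` and `beta = 1` to within a few percent from
this single noisy measurement pair (folding more periods or measurements
tightens it).

The run container round-trips through `write_run()`/`read_run()`; loops
and per-harmonic tables export to CSV. A thin command-line wrapper over
these functions is installed at `inst/cli/mpskit` (subcommands `design`,
`simulate`, `spectroscopy`, `loop`, `relaxometry`, `magnetometry`,
`sysmatrix`).

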