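Package: mpskit
Title: Simulation and Analysis for Magnetic Particle Spectroscopy, Relaxometry, and Loop Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for desk-scale emulation and analysis of a magnetic particle
    spectrometer/relaxometer/hysteresis-loop tracer. Includes closed-form
    hardware design-budget calculations (feedthrough moment, harmonic purity,
    shielding, transformer core flux, skin depth, duty cycle, noise referral),
    a Langevin/Debye nanoparticle magnetization model with relaxation-kernel
    convolution, a synthetic instrument-signal generator (drive and bias
    waveforms, inductive receive-chain transfer function, feedthrough, drift,
    noise, sample-in/out measurement schedules), and the five analysis modes:
    harmonic spectroscopy with GLM-based in/out detection, relaxometry
    (time-constant fitting), dynamic hysteresis loop tracing, spectrogram-based
    quasistatic magnetometry, and one-dimensional system-matrix extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
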