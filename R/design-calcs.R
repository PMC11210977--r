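# Vacuum permeability, H/m
MU0 <- 4e-7 * pi

.check_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", what), call. = FALSE)
  invisible(x)
}

.check_nonneg <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("`%s` must be a single non-negative finite number", what), call. = FALSE)
  invisible(x)
}

#' Drive-coil specification
#'
#' Geometry and coupling parameters of the drive coil as seen by the receive
#' chain: the ampere-turns and cross-section that set its equivalent
#' feedthrough moment, the residual gradiometer coupling, and the winding and
#' shield radii that set the shielding-tube efficiency penalty.
#'
#' @param amp_turns Drive-coil ampere-turns N*I (A-turns).
#' @param cross_section_area Coil cross-sectional area (m^2).
#' @param gradiometer_attenuation Residual linear coupling of the gradiometric
#'   receive coil to the drive field (e.g. `1e-3` for -60 dB). Must lie in (0, 1].
#' @param mean_winding_radius Mean drive winding radius (m).
#' @param shield_inner_radius Inner radius of the conductive shielding tube (m).
#' @return An object of class `drive_coil_spec`.
#' @examples
#' drive_coil_spec(250, 3e-4, 1e-3)
#' @export
drive_coil_spec <- function(amp_turns, cross_section_area, gradiometer_attenuation,
                            mean_winding_radius = 0.012, shield_inner_radius = 0.0185) {
  .check_pos(amp_turns, "amp_turns")
  .check_pos(cross_section_area, "cross_section_area")
  .check_pos(gradiometer_attenuation, "gradiometer_attenuation")
  if (gradiometer_attenuation > 1)
    stop("`gradiometer_attenuation` must lie in (0, 1]", call. = FALSE)
  .check_pos(mean_winding_radius, "mean_winding_radius")
  .check_pos(shield_inner_radius, "shield_inner_radius")
  if (mean_winding_radius >= shield_inner_radius)
    stop("`mean_winding_radius` must be smaller than `shield_inner_radius`", call. = FALSE)
  structure(list(amp_turns = amp_turns,
                 cross_section_area = cross_section_area,
                 gradiometer_attenuation = gradiometer_attenuation,
                 mean_winding_radius = mean_winding_radius,
                 shield_inner_radius = shield_inner_radius),
            class = "drive_coil_spec")
}

#' Sample specification
#'
#' @param iron_mass Iron mass of the sample (kg).
#' @param saturation_magnetization_per_mass Saturation magnetization per unit
#'   iron mass (Am^2/kg); about 110 for typical MPI tracers.
#' @param third_to_first_ratio Ratio of the particle's third-harmonic to
#'   fundamental response amplitude (S_3/1), in \[0, 1\].
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(iron_mass, saturation_magnetization_per_mass = 110,
                        third_to_first_ratio = 1 / 3) {
  .check_nonneg(iron_mass, "iron_mass")
  .check_pos(saturation_magnetization_per_mass, "saturation_magnetization_per_mass")
  .check_nonneg(third_to_first_ratio, "third_to_first_ratio")
  if (third_to_first_ratio > 1)
    stop("`third_to_first_ratio` must lie in [0, 1]", call. = FALSE)
  structure(list(iron_mass = iron_mass,
                 saturation_magnetization_per_mass = saturation_magnetization_per_mass,
                 third_to_first_ratio = third_to_first_ratio),
            class = "sample_spec")
}

#' Transformer specification (cantilever model)
#'
#' @param leakage_inductance Series leakage inductance (H).
#' @param magnetizing_inductance Shunt magnetizing inductance (H).
#' @param inductance_ratio Side-A to side-B inductance ratio (dimensionless).
#' @param turns_ratio Turns ratio; must satisfy turns_ratio^2 == inductance_ratio
#'   within 1 percent. Defaults to `sqrt(inductance_ratio)`.
#' @return An object of class `transformer_spec`.
#' @export
transformer_spec <- function(leakage_inductance, magnetizing_inductance,
                             inductance_ratio, turns_ratio = sqrt(inductance_ratio)) {
  .check_pos(leakage_inductance, "leakage_inductance")
  .check_pos(magnetizing_inductance, "magnetizing_inductance")
  .check_pos(inductance_ratio, "inductance_ratio")
  .check_pos(turns_ratio, "turns_ratio")
  if (abs(turns_ratio^2 - inductance_ratio) > 0.01 * inductance_ratio)
    stop("`turns_ratio`^2 must equal `inductance_ratio` within 1%", call. = FALSE)
  structure(list(leakage_inductance = leakage_inductance,
                 magnetizing_inductance = magnetizing_inductance,
                 inductance_ratio = inductance_ratio,
                 turns_ratio = turns_ratio),
            class = "transformer_spec")
}

#' Amplifier noise specification
#'
#' @param voltage_noise_density Input-referred voltage noise density (V/sqrt(Hz)).
#' @param current_noise_density Input-referred current noise density (A/sqrt(Hz)).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(voltage_noise_density, current_noise_density) {
  .check_nonneg(voltage_noise_density, "voltage_noise_density")
  .check_nonneg(current_noise_density, "current_noise_density")
  structure(list(voltage_noise_density = voltage_noise_density,
                 current_noise_density = current_noise_density),
            class = "noise_spec")
}

#' Equivalent feedthrough moment of the drive field
#'
#' The drive field couples into the gradiometric receive coil with residual
#' attenuation A_Grad; its equivalent magnetic moment is N*I * A * A_Grad.
#' This is the quantity against which a sample's moment competes.
#'
#' @param coil A [drive_coil_spec()].
#' @return Equivalent feedthrough moment (Am^2).
#' @examples
#' feedthrough_moment(drive_coil_spec(250, 3e-4, 1e-3)) # 7.5e-5 Am^2
#' @export
feedthrough_moment <- function(coil) {
  stopifnot(inherits(coil, "drive_coil_spec"))
  coil$amp_turns * coil$cross_section_area * coil$gradiometer_attenuation
}

#' Drive-waveform purity requirement
#'
#' Ratio of allowable third-harmonic drive-field content to the fundamental
#' such that the detected drive 3f0 stays at the level of the sample's
#' third-harmonic moment: m_Fe * M_sat * S_3/1 / (N*I * A * A_Grad).
#'
#' @param coil A [drive_coil_spec()].
#' @param sample A [sample_spec()].
#' @return Dimensionless linear ratio; convert with [to_dbc()].
#' @examples
#' p <- purity_requirement(drive_coil_spec(250, 3e-4, 1e-3),
#'                         sample_spec(1e-11, 110, 1 / 3))
#' to_dbc(p) # about -106 dBc
#' @export
purity_requirement <- function(coil, sample) {
  stopifnot(inherits(coil, "drive_coil_spec"), inherits(sample, "sample_spec"))
  md <- feedthrough_moment(coil)
  if (md == 0) stop("feedthrough moment is zero; purity ratio undefined", call. = FALSE)
  sample$iron_mass * sample$saturation_magnetization_per_mass *
    sample$third_to_first_ratio / md
}

#' Convert an amplitude ratio to dB relative to carrier
#'
#' Amplitude convention: 20*log10(ratio).
#'
#' @param ratio Linear amplitude ratio (> 0).
#' @return Value in dBc.
#' @export
to_dbc <- function(ratio) {
  .check_pos(ratio, "ratio")
  20 * log10(ratio)
}

#' Field attenuation of a solenoid inside a conductive shielding tube
#'
#' The center field of a finite solenoid inside a long shield many skin
#' depths thick is reduced by the factor 1 - r_solenoid^2 / r_shield^2.
#'
#' @param coil A [drive_coil_spec()]; uses `mean_winding_radius` and
#'   `shield_inner_radius`.
#' @return Remaining-field factor in \[0, 1); percent reduction is
#'   `100 * (1 - factor)`.
#' @export
shield_attenuation_factor <- function(coil) {
  stopifnot(inherits(coil, "drive_coil_spec"))
  1 - coil$mean_winding_radius^2 / coil$shield_inner_radius^2
}

#' Peak transformer core flux density
#'
#' B_peak = V_peak / (2 pi f N A_e). Keeping this well below core saturation
#' (< 5 percent) limits harmonic generation in the drive filter's transformer.
#'
#' @param v_peak Peak primary voltage (V); may be zero.
#' @param freq Frequency (Hz).
#' @param turns Primary turns.
#' @param core_area Effective core cross-section A_e (m^2).
#' @return Peak flux density (T).
#' @examples
#' core_flux_peak(20, 23815, 44, 306e-6) # about 9.9 mT
#' @export
core_flux_peak <- function(v_peak, freq, turns, core_area) {
  .check_nonneg(v_peak, "v_peak")
  .check_pos(freq, "freq")
  .check_pos(turns, "turns")
  .check_pos(core_area, "core_area")
  v_peak / (2 * pi * freq * turns * core_area)
}

#' Primary turns required for a target core flux density
#'
#' Inverse of [core_flux_peak()]: N = V_peak / (2 pi f B_peak A_e). Returns
#' the exact (non-integer) formula value.
#'
#' @param v_peak Peak primary voltage (V).
#' @param freq Frequency (Hz).
#' @param b_peak Target peak flux density (T).
#' @param core_area Effective core cross-section (m^2).
#' @return Required turns (exact value, not rounded).
#' @export
turns_for_flux <- function(v_peak, freq, b_peak, core_area) {
  .check_pos(v_peak, "v_peak")
  .check_pos(freq, "freq")
  .check_pos(b_peak, "b_peak")
  .check_pos(core_area, "core_area")
  v_peak / (2 * pi * freq * b_peak * core_area)
}

#' Skin depth in a conductor
#'
#' delta = sqrt(rho / (pi f mu0)). Copper at 20 C (rho = 1.68e-8 Ohm m) gives
#' 0.42 mm at 23.8 kHz, which sets the Litz strand gauge.
#'
#' @param resistivity Conductor resistivity (Ohm m). Default copper, 20 C.
#' @param freq Frequency (Hz).
#' @return Skin depth (m).
#' @export
skin_depth <- function(resistivity = 1.68e-8, freq) {
  .check_pos(resistivity, "resistivity")
  .check_pos(freq, "freq")
  sqrt(resistivity / (pi * freq * MU0))
}

#' Duty cycle for equal resistive power dissipation
#'
#' Power scales with current squared, so running at current density j_target
#' with the dissipation of a continuously tolerable j_reference requires a
#' duty cycle of (j_reference / j_target)^2.
#'
#' @param j_target Required current density (A/mm^2).
#' @param j_reference Continuously tolerable current density (A/mm^2).
#' @return Duty-cycle fraction.
#' @examples
#' duty_cycle_for_equal_power(15, 5) # about 11%
#' @export
duty_cycle_for_equal_power <- function(j_target, j_reference) {
  .check_pos(j_target, "j_target")
  .check_pos(j_reference, "j_reference")
  (j_reference / j_target)^2
}

#' Refer amplifier noise through a matching transformer
#'
#' Referring preamp input noise across a step-up transformer of ratio n
#' (secondary:primary) divides voltage noise by n and multiplies current
#' noise by n.
#'
#' @param noise A [noise_spec()].
#' @param turns_ratio Step-up turns ratio (> 0).
#' @return A [noise_spec()] referred to the primary (coil) side.
#' @examples
#' refer_noise_through_transformer(noise_spec(3.3e-9, 1.5e-12), 4.35)
#' @export
refer_noise_through_transformer <- function(noise, turns_ratio) {
  stopifnot(inherits(noise, "noise_spec"))
  .check_pos(turns_ratio, "turns_ratio")
  noise_spec(noise$voltage_noise_density / turns_ratio,
             noise$current_noise_density * turns_ratio)
}

#' Turns ratio implied by an inductance ratio
#'
#' Inductance scales with turns squared, so the turns ratio is the square
#' root of the inductance ratio.
#'
#' @param l_ratio Inductance ratio (> 0).
#' @return Turns ratio.
#' @examples
#' turns_ratio_from_inductance_ratio(18.9) # 4.35
#' @export
turns_ratio_from_inductance_ratio <- function(l_ratio) {
  .check_pos(l_ratio, "l_ratio")
  sqrt(l_ratio)
}

#' Inductive reactance
#'
#' @param inductance Inductance (H).
#' @param freq Frequency (Hz); zero allowed.
#' @return Reactance 2 pi f L (Ohm).
#' @export
reactance <- function(inductance, freq) {
  .check_pos(inductance, "inductance")
  .check_nonneg(freq, "freq")
  2 * pi * freq * inductance
}

#' Full design-budget report
#'
#' Evaluates every closed-form design calculation for a given drive coil,
#' reference sample, receive matching transformer, preamp noise, and drive
#' filter transformer, and returns them in one named list (used by the
#' `design` CLI subcommand).
#'
#' @param coil A [drive_coil_spec()].
#' @param sample A [sample_spec()].
#' @param rx_noise A [noise_spec()] for the preamp input.
#' @param rx_inductance_ratio Receive matching-transformer inductance ratio
#'   (coil side : preamp side expressed as step-up factor).
#' @param filter_v_peak,filter_freq,filter_flux_peak,filter_core_area Drive
#'   filter transformer design point (V, Hz, T, m^2).
#' @param j_target,j_reference Winding current densities (A/mm^2).
#' @return Named list of computed design quantities.
#' @export
design_report <- function(coil = drive_coil_spec(250, 3e-4, 1e-3),
                          sample = sample_spec(1e-11, 110, 1 / 3),
                          rx_noise = noise_spec(3.3e-9, 1.5e-12),
                          rx_inductance_ratio = 18.9,
                          filter_v_peak = 20, filter_freq = 23815,
                          filter_flux_peak = 0.010, filter_core_area = 306e-6,
                          j_target = 15, j_reference = 5) {
  n_rx <- turns_ratio_from_inductance_ratio(rx_inductance_ratio)
  referred <- refer_noise_through_transformer(rx_noise, n_rx)
  purity <- purity_requirement(coil, sample)
  list(
    feedthrough_moment_Am2 = feedthrough_moment(coil),
    purity_ratio = purity,
    purity_dbc = to_dbc(purity),
    shield_factor = shield_attenuation_factor(coil),
    shield_reduction_pct = 100 * (1 - shield_attenuation_factor(coil)),
    skin_depth_m = skin_depth(freq = filter_freq),
    duty_cycle = duty_cycle_for_equal_power(j_target, j_reference),
    core_flux_turns = turns_for_flux(filter_v_peak, filter_freq,
                                     filter_flux_peak, filter_core_area),
    rx_turns_ratio = n_rx,
    referred_voltage_noise = referred$voltage_noise_density,
    referred_current_noise = referred$current_noise_density
  )
}
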