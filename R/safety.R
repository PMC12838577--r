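#' Biphasic stimulation pulse specification
#'
#' Physical parameters of a charge-balanced biphasic stimulation pulse and
#' the electrode that delivers it; defaults describe a +/-300 mV, 200 us
#' per phase pulse on a 30 um platinum-nanoparticle-coated site with ~9 kOhm
#' impedance.
#'
#' @param amplitude_v Pulse amplitude per phase, volts.
#' @param impedance_ohm Electrode impedance magnitude at the relevant
#'   frequency, ohms.
#' @param phase_width_s Single-phase width, seconds.
#' @param electrode_diameter_m Electrode site diameter, meters.
#' @param frequency_hz,n_pulses Stimulation schedule metadata.
#' @return A list of class `stim_pulse_spec`.
#' @export
stim_pulse_spec <- function(amplitude_v = 0.3, impedance_ohm = 9000,
                            phase_width_s = 200e-6,
                            electrode_diameter_m = 30e-6,
                            frequency_hz = 40, n_pulses = 100) {
  vals <- c(amplitude_v = amplitude_v, impedance_ohm = impedance_ohm,
            phase_width_s = phase_width_s,
            electrode_diameter_m = electrode_diameter_m)
  if (any(!is.finite(vals)) || any(vals < 0) ||
      impedance_ohm <= 0 || phase_width_s <= 0 ||
      electrode_diameter_m <= 0) {
    abort("pulse parameters must be positive (amplitude may be zero).",
          class = "spikesync_validation_error")
  }
  structure(
    list(amplitude_v = amplitude_v, impedance_ohm = impedance_ohm,
         phase_width_s = phase_width_s,
         electrode_diameter_m = electrode_diameter_m,
         frequency_hz = frequency_hz, n_pulses = n_pulses),
    class = "stim_pulse_spec"
  )
}

#' Charge per phase
#'
#' Estimates the per-phase current as `V / Z` (scalar impedance magnitude)
#' and the charge as current times phase width, reported in nanocoulombs.
#'
#' @param spec A [stim_pulse_spec()], or the amplitude in volts when the
#'   remaining arguments are given.
#' @param impedance_ohm,phase_width_s Used when `spec` is a bare
#'   amplitude.
#' @return Charge per phase, nC.
#' @export
#' @examples
#' charge_per_phase(0.3, 9000, 200e-6)  # 6.67 nC
charge_per_phase <- function(spec, impedance_ohm = NULL,
                             phase_width_s = NULL) {
  if (inherits(spec, "stim_pulse_spec")) {
    amplitude_v <- spec$amplitude_v
    impedance_ohm <- spec$impedance_ohm
    phase_width_s <- spec$phase_width_s
  } else {
    amplitude_v <- spec
  }
  if (is.null(impedance_ohm) || impedance_ohm <= 0) {
    abort("impedance_ohm must be positive.",
          class = "spikesync_validation_error")
  }
  (amplitude_v / impedance_ohm) * phase_width_s * 1e9
}

#' Geometric charge density
#'
#' Charge per phase divided by the electrode's geometric surface area
#' (a disc of the given diameter), in mC/cm^2.
#'
#' @param charge_nC Charge per phase, nC.
#' @param diameter_m Electrode site diameter, meters.
#' @return Charge density, mC/cm^2.
#' @export
#' @examples
#' charge_density(6.67, 30e-6)  # ~0.94 mC/cm^2
charge_density <- function(charge_nC, diameter_m) {
  if (diameter_m <= 0) {
    abort("diameter_m must be positive.",
          class = "spikesync_validation_error")
  }
  area_cm2 <- pi * (diameter_m / 2 * 100)^2
  (charge_nC * 1e-6) / area_cm2  # nC -> mC
}

#' Shannon criterion k
#'
#' `k = log10(D) + log10(Q)` with the conventional units: charge density D
#' in uC/cm^2 per phase and charge Q in uC per phase. Electrode damage is
#' empirically associated with k above ~1.5.
#'
#' @param charge_nC Charge per phase, nC.
#' @param density_mC_cm2 Geometric charge density, mC/cm^2.
#' @return The Shannon k value.
#' @export
shannon_k <- function(charge_nC, density_mC_cm2) {
  if (charge_nC <= 0 || density_mC_cm2 <= 0) {
    abort("charge and density must be positive for the Shannon criterion.",
          class = "spikesync_validation_error")
  }
  q_uC <- charge_nC * 1e-3
  d_uC_cm2 <- density_mC_cm2 * 1e3
  log10(d_uC_cm2) + log10(q_uC)
}

#' Stimulation charge-safety report
#'
#' Computes charge per phase, geometric charge density and Shannon k for a
#' pulse specification and issues a verdict: `"SAFE"` when `k <= k_limit`
#' (boundary inclusive), `"UNSAFE"` otherwise.
#'
#' @param spec A [stim_pulse_spec()].
#' @param k_limit Shannon damage threshold (default 1.5).
#' @return One-row tibble: `charge_nC`, `density_mC_cm2`, `shannon_k`,
#'   `k_limit`, `verdict`.
#' @export
#' @examples
#' safety_report(stim_pulse_spec())
safety_report <- function(spec, k_limit = 1.5) {
  stopifnot(inherits(spec, "stim_pulse_spec"))
  q <- charge_per_phase(spec)
  d <- charge_density(q, spec$electrode_diameter_m)
  k <- shannon_k(q, d)
  tibble(charge_nC = q, density_mC_cm2 = d, shannon_k = k,
         k_limit = k_limit,
         verdict = if (k <= k_limit) "SAFE" else "UNSAFE")
}

#' Impedance fold change
#'
#' Ratio of two impedance magnitudes (e.g. bare vs nanoparticle-coated
#' electrode means at 1 kHz).
#'
#' @param z_before,z_after Impedances in the same units (> 0).
#' @return `z_before / z_after`.
#' @export
#' @examples
#' impedance_fold_change(877.4, 9.3)  # ~94-fold
impedance_fold_change <- function(z_before, z_after) {
  if (z_before <= 0 || z_after <= 0) {
    abort("impedances must be positive.",
          class = "spikesync_validation_error")
  }
  z_before / z_after
}
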