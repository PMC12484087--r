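#' Passive electrical parameters of the cell membrane
#'
#' Container for the fixed elements of the membrane equivalent circuit: the
#' baseline membrane capacitance, the (constant) membrane resistance, the
#' resting potential driving the leak, and the baseline surface potential.
#' The unit system is fixed to mV / pF / GOhm / ms throughout the package, so
#' the passive time constant `rm * cm0` is directly in milliseconds.
#'
#' Defaults are the package's calibrated reference cell: `cm0 = 26.67` pF
#' (chosen so that a -15\% light-induced change is a 4 pF drop), `rm = 1` GOhm
#' (typical HEK-293 whole-cell value, giving a ~27 ms passive time constant),
#' `vr = -60` mV and a baseline surface potential `vs0 = +15` mV (see the
#' methods vignette for the calibration).
#'
#' @param cm0 Baseline membrane capacitance, pF. Must be positive.
#' @param rm Membrane resistance, GOhm. Must be positive.
#' @param vr Resting membrane potential, mV.
#' @param vs0 Baseline surface potential, mV.
#' @return An object of class `membrane_params`.
#' @examples
#' mem <- membrane_params()
#' mem$rm * mem$cm0   # passive time constant, ms
#' @export
membrane_params <- function(cm0 = 26.67, rm = 1.0, vr = -60, vs0 = 15) {
  stop_if_bad(
    is_num1(cm0) && cm0 > 0, "cm0 must be a single finite positive number (pF)",
    is_num1(rm) && rm > 0, "rm must be a single finite positive number (GOhm)",
    is_num1(vr), "vr must be a single finite number (mV)",
    is_num1(vs0), "vs0 must be a single finite number (mV)"
  )
  tau <- rm * cm0
  if (!is.finite(tau) || tau <= 0)
    stop("membrane time constant rm*cm0 must be finite and positive")
  structure(list(cm0 = cm0, rm = rm, vr = vr, vs0 = vs0),
            class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("Membrane parameters:\n")
  cat(sprintf("  C_m0 = %g pF, R_m = %g GOhm (tau = %g ms)\n",
              x$cm0, x$rm, x$rm * x$cm0))
  cat(sprintf("  V_r  = %g mV, V_s0 = %g mV\n", x$vr, x$vs0))
  invisible(x)
}

#' Light-coupled perturbation parameters of the photoswitch
#'
#' Signed amplitudes and first-order kinetic time constants of the two
#' light-driven perturbations: the relative capacitance change `dcm_rel`
#' (dimensionless, at full cis occupancy; -0.15 means a 15\% drop) and the
#' surface-potential step `dvs` (mV at full cis occupancy and unit field
#' scaling). Each pathway carries its own rise/decay pair so the two
#' occupancy drives can be fitted independently even though the photophysics
#' suggests similar kinetics.
#'
#' @param dcm_rel Fractional capacitance change at full cis occupancy
#'   (signed, dimensionless). `1 + dcm_rel` must be positive.
#' @param dvs Surface-potential step at full cis occupancy, mV (signed;
#'   positive is depolarizing).
#' @param tau_on_c,tau_off_c Rise/decay time constants of the capacitance
#'   drive, ms.
#' @param tau_on_s,tau_off_s Rise/decay time constants of the
#'   surface-potential drive, ms.
#' @return An object of class `photoswitch_params`.
#' @export
photoswitch_params <- function(dcm_rel = -0.15, dvs = 5,
                               tau_on_c = 0.9, tau_off_c = 100,
                               tau_on_s = 4, tau_off_s = 30) {
  stop_if_bad(
    is_num1(dcm_rel), "dcm_rel must be a single finite number",
    is_num1(dvs), "dvs must be a single finite number (mV)",
    is_num1(tau_on_c) && tau_on_c > 0, "tau_on_c must be positive (ms)",
    is_num1(tau_off_c) && tau_off_c > 0, "tau_off_c must be positive (ms)",
    is_num1(tau_on_s) && tau_on_s > 0, "tau_on_s must be positive (ms)",
    is_num1(tau_off_s) && tau_off_s > 0, "tau_off_s must be positive (ms)"
  )
  if (1 + dcm_rel <= 0)
    stop("1 + dcm_rel must be positive (capacitance must stay positive)")
  structure(list(dcm_rel = dcm_rel, dvs = dvs,
                 tau_on_c = tau_on_c, tau_off_c = tau_off_c,
                 tau_on_s = tau_on_s, tau_off_s = tau_off_s),
            class = "photoswitch_params")
}

#' @export
print.photoswitch_params <- function(x, ...) {
  cat("Photoswitch parameters:\n")
  cat(sprintf("  dC_m/C_m0 = %+g (at full cis), dV_s = %+g mV\n",
              x$dcm_rel, x$dvs))
  cat(sprintf("  C_m kinetics: tau_on = %g ms, tau_off = %g ms\n",
              x$tau_on_c, x$tau_off_c))
  cat(sprintf("  V_s kinetics: tau_on = %g ms, tau_off = %g ms\n",
              x$tau_on_s, x$tau_off_s))
  invisible(x)
}

#' Light stimulation protocol
#'
#' A single rectangular light pulse. Wavelength and irradiance are carried as
#' metadata only (rates are not coupled to intensity; the model is calibrated
#' at one irradiance).
#'
#' @param t_on Pulse onset, ms from window start. At least 50 ms of pre-pulse
#'   baseline is required by the trace metrics, so `t_on >= 50` by default.
#' @param duration Pulse duration, ms. Must be positive.
#' @param wavelength Wavelength, nm (metadata).
#' @param irradiance Power density, mW/mm^2 (metadata).
#' @return An object of class `light_protocol`.
#' @export
light_protocol <- function(t_on = 50, duration = 20,
                           wavelength = 470, irradiance = 50) {
  stop_if_bad(
    is_num1(t_on) && t_on >= 0, "t_on must be a single non-negative number (ms)",
    is_num1(duration) && duration > 0, "duration must be positive (ms)",
    is_num1(wavelength) && wavelength > 0, "wavelength must be positive (nm)",
    is_num1(irradiance) && irradiance >= 0, "irradiance must be non-negative (mW/mm^2)"
  )
  structure(list(t_on = t_on, duration = duration,
                 wavelength = wavelength, irradiance = irradiance),
            class = "light_protocol")
}

#' @export
print.light_protocol <- function(x, ...) {
  cat(sprintf("Light pulse: %g ms at t = %g ms (%g nm, %g mW/mm^2)\n",
              x$duration, x$t_on, x$wavelength, x$irradiance))
  invisible(x)
}

#' Recording noise model for synthetic traces
#'
#' Additive Gaussian noise (standard deviation after low-pass filtering) plus
#' an optional linear baseline drift, with a seed that makes every generated
#' trace reproducible.
#'
#' @param sigma Noise standard deviation after filtering, mV. Non-negative.
#' @param drift_rate Linear baseline drift, mV/s.
#' @param seed Integer seed; the same seed always yields the same trace.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.3, drift_rate = 0, seed = 1) {
  stop_if_bad(
    is_num1(sigma) && sigma >= 0, "sigma must be a single non-negative number (mV)",
    is_num1(drift_rate), "drift_rate must be a single finite number (mV/s)",
    is_num1(seed) && seed == round(seed), "seed must be a single integer"
  )
  structure(list(sigma = sigma, drift_rate = drift_rate, seed = as.integer(seed)),
            class = "noise_model")
}

# internal validation helpers ------------------------------------------------

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# stop_if_bad(cond1, msg1, cond2, msg2, ...): collect every violated message
stop_if_bad <- function(...) {
  args <- list(...)
  conds <- args[seq(1, length(args), by = 2)]
  msgs <- args[seq(2, length(args), by = 2)]
  bad <- !vapply(conds, isTRUE, logical(1))
  if (any(bad))
    stop(paste(unlist(msgs[bad]), collapse = "; "), call. = FALSE)
  invisible(TRUE)
}
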