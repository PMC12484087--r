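#' Cis-isomer occupancy kinetics under a rectangular light pulse
#'
#' First-order two-state kinetics with a photo-driven forward rate during the
#' pulse and a thermal back rate throughout:
#' `dx/dt = (1 - x)/tau_on - x/tau_off` while the light is on and
#' `dx/dt = -x/tau_off` afterwards, with `x = 0` in the dark-adapted state
#' before the pulse. The solution is piecewise single-exponential: during
#' the pulse `x(t) = x_inf * (1 - exp(-(t - t_on)/tau_eff))` with plateau
#' `x_inf = tau_off/(tau_on + tau_off)` and effective rise time
#' `tau_eff = tau_on*tau_off/(tau_on + tau_off)`; after the pulse the
#' occupancy decays exponentially with `tau_off` from its value at pulse
#' offset. Both the occupancy and its exact analytic derivative are returned
#' as vectorized functions of time.
#'
#' @param protocol A [light_protocol()].
#' @param tau_on Rise time constant during illumination, ms.
#' @param tau_off Thermal decay time constant, ms.
#' @return An object of class `cis_occupancy`: a list with vectorized
#'   functions `x_of_t(t)` and `dx_dt(t)` plus the kinetic constants.
#' @examples
#' occ <- cis_occupancy(light_protocol(), tau_on = 2, tau_off = 100)
#' occ$x_of_t(c(0, 60, 300))   # dark, near-plateau, decaying
#' @export
cis_occupancy <- function(protocol, tau_on, tau_off) {
  stopifnot(inherits(protocol, "light_protocol"))
  stop_if_bad(
    is_num1(tau_on) && tau_on > 0, "tau_on must be positive (ms)",
    is_num1(tau_off) && tau_off > 0, "tau_off must be positive (ms)"
  )
  t_on <- protocol$t_on
  t_off <- protocol$t_on + protocol$duration
  x_inf <- tau_off / (tau_on + tau_off)
  tau_eff <- tau_on * tau_off / (tau_on + tau_off)
  x_end <- x_inf * (1 - exp(-protocol$duration / tau_eff))  # value at offset

  x_of_t <- function(t) {
    x <- numeric(length(t))
    inl <- t >= t_on & t <= t_off
    aft <- t > t_off
    x[inl] <- x_inf * (1 - exp(-(t[inl] - t_on) / tau_eff))
    x[aft] <- x_end * exp(-(t[aft] - t_off) / tau_off)
    x
  }
  dx_dt <- function(t) {
    d <- numeric(length(t))
    inl <- t >= t_on & t <= t_off
    aft <- t > t_off
    d[inl] <- (x_inf / tau_eff) * exp(-(t[inl] - t_on) / tau_eff)
    d[aft] <- -(x_end / tau_off) * exp(-(t[aft] - t_off) / tau_off)
    d
  }
  structure(list(x_of_t = x_of_t, dx_dt = dx_dt,
                 tau_on = tau_on, tau_off = tau_off,
                 t_on = t_on, t_off = t_off,
                 x_inf = x_inf, tau_eff = tau_eff, x_end = x_end),
            class = "cis_occupancy")
}

#' Time-dependent circuit coefficients
#'
#' Bundle of the four functions the membrane ODE needs: `C_m(t)`, its exact
#' derivative, `V_s(t)` and its exact derivative. Usually built from
#' photoswitch kinetics with [build_coefficients()]; [constant_coefficients()]
#' gives the no-light special case. `breaks` marks times where the
#' derivatives are discontinuous (pulse onset/offset) so the integrator can
#' split there, and `seg_tau` gives the smallest kinetic time constant active
#' in each inter-break segment (used for the solver's maximum step).
#'
#' @param cm_of_t,dcm_dt,vs_of_t,dvs_dt Vectorized functions of time (ms)
#'   returning pF, pF/ms, mV and mV/ms respectively.
#' @param breaks Numeric vector of derivative discontinuity times, ms.
#' @param seg_tau Numeric vector, `length(breaks) + 1`: smallest active time
#'   constant per segment (ms), or `Inf` where only the passive membrane sets
#'   the timescale.
#' @return An object of class `circuit_coefficients`.
#' @export
circuit_coefficients <- function(cm_of_t, dcm_dt, vs_of_t, dvs_dt,
                                 breaks = numeric(0), seg_tau = Inf) {
  stopifnot(is.function(cm_of_t), is.function(dcm_dt),
            is.function(vs_of_t), is.function(dvs_dt))
  if (length(seg_tau) != length(breaks) + 1L)
    stop("seg_tau must have one entry per segment (length(breaks) + 1)")
  structure(list(cm_of_t = cm_of_t, dcm_dt = dcm_dt,
                 vs_of_t = vs_of_t, dvs_dt = dvs_dt,
                 breaks = breaks, seg_tau = seg_tau),
            class = "circuit_coefficients")
}

#' @rdname circuit_coefficients
#' @param cm0 Constant capacitance, pF.
#' @param vs0 Constant surface potential, mV.
#' @export
constant_coefficients <- function(cm0, vs0) {
  stop_if_bad(is_num1(cm0) && cm0 > 0, "cm0 must be positive (pF)",
              is_num1(vs0), "vs0 must be finite (mV)")
  force(cm0); force(vs0)
  circuit_coefficients(
    cm_of_t = function(t) rep_len(cm0, length(t)),
    dcm_dt = function(t) numeric(length(t)),
    vs_of_t = function(t) rep_len(vs0, length(t)),
    dvs_dt = function(t) numeric(length(t))
  )
}

#' Assemble C_m(t) and V_s(t) from photoswitch kinetics
#'
#' The two light-driven perturbations share the same functional form but
#' carry independent occupancy drives:
#' `C_m(t) = cm0 * (1 + dcm_rel * x_C(t))` and
#' `V_s(t) = vs0 + dvs * vs_scale * x_S(t)`, where `x_C` and `x_S` are
#' [cis_occupancy()] solutions with their own rise/decay constants and
#' `vs_scale` is the field-strength multiplier from [field_scale()]
#' (1 disables scaling). Derivatives are assembled from the closed-form
#' occupancy derivatives, never by numerical differentiation.
#'
#' @param mem A [membrane_params()].
#' @param ps A [photoswitch_params()].
#' @param protocol A [light_protocol()].
#' @param vs_scale Non-negative field-scaling multiplier for the
#'   surface-potential amplitude.
#' @return A [circuit_coefficients()] object.
#' @examples
#' co <- build_coefficients(membrane_params(), photoswitch_params(),
#'                          light_protocol())
#' co$cm_of_t(c(0, 70))   # baseline vs near end of a 20 ms pulse
#' @export
build_coefficients <- function(mem, ps, protocol, vs_scale = 1) {
  stopifnot(inherits(mem, "membrane_params"),
            inherits(ps, "photoswitch_params"),
            inherits(protocol, "light_protocol"))
  stop_if_bad(is_num1(vs_scale) && vs_scale >= 0,
              "vs_scale must be a single non-negative number")
  xc <- cis_occupancy(protocol, ps$tau_on_c, ps$tau_off_c)
  xs <- cis_occupancy(protocol, ps$tau_on_s, ps$tau_off_s)
  cm0 <- mem$cm0; vs0 <- mem$vs0
  dcm_rel <- ps$dcm_rel; dvs_amp <- ps$dvs * vs_scale
  # occupancy is in [0, 1], so the extreme capacitance is cm0*(1 + dcm_rel)
  if (cm0 * (1 + min(0, dcm_rel)) <= 0)
    stop("resulting C_m(t) would be non-positive; check dcm_rel")
  co <- circuit_coefficients(
    cm_of_t = function(t) cm0 * (1 + dcm_rel * xc$x_of_t(t)),
    dcm_dt = function(t) cm0 * dcm_rel * xc$dx_dt(t),
    vs_of_t = function(t) vs0 + dvs_amp * xs$x_of_t(t),
    dvs_dt = function(t) dvs_amp * xs$dx_dt(t),
    breaks = c(protocol$t_on, protocol$t_on + protocol$duration),
    seg_tau = c(Inf,
                min(ps$tau_on_c, ps$tau_off_c, ps$tau_on_s, ps$tau_off_s),
                min(ps$tau_off_c, ps$tau_off_s))
  )
  co
}
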