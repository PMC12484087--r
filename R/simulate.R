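#' Right-hand side of the membrane equation
#'
#' The membrane equivalent circuit with a time-varying capacitance and a
#' time-varying series surface-potential generator obeys
#' \deqn{dV_m/dt = dV_s/dt - (dC_m/dt)\,(V_m - V_s(t))/C_m(t) +
#'       (V_r - V_m)/(C_m(t) R_m)}
#' in the package's mV / pF / GOhm / ms unit system (GOhm x pF = ms). The
#' middle term is the charge-conservation coupling: when the capacitance
#' drops, the stored charge `(V_m - V_s) C_m` is conserved on fast
#' timescales, so `V_m - V_s` must grow in magnitude; the last term is the
#' ohmic leak pulling `V_m` back to rest.
#'
#' @param vm Membrane potential, mV.
#' @param t Time, ms.
#' @param coeffs A [circuit_coefficients()] object valid at `t`.
#' @param params A [membrane_params()] (supplies `vr` and `rm`).
#' @return `dV_m/dt` in mV/ms.
#' @export
membrane_rhs <- function(vm, t, coeffs, params) {
  stopifnot(inherits(coeffs, "circuit_coefficients"),
            inherits(params, "membrane_params"))
  if (!all(is.finite(vm)) || !all(is.finite(t)))
    stop("non-finite vm or t")
  cm <- coeffs$cm_of_t(t)
  if (any(!is.finite(cm)) || any(cm <= 0))
    stop("C_m(t) must be finite and positive at t = ", t[1])
  coeffs$dvs_dt(t) -
    coeffs$dcm_dt(t) * (vm - coeffs$vs_of_t(t)) / cm +
    (params$vr - vm) / (cm * params$rm)
}

# segment boundaries inside [t0, t1] given coefficient breaks
seg_bounds <- function(coeffs, t0, t1) {
  br <- coeffs$breaks
  inside <- br[br > t0 & br < t1]
  sort(unique(c(t0, inside, t1)))
}

# smallest active time constant for the segment starting just after `t0`
seg_tau_at <- function(coeffs, t0, params) {
  br <- coeffs$breaks
  idx <- findInterval(t0 + 1e-12, c(-Inf, br))  # 1..nseg
  tau <- coeffs$seg_tau[idx]
  min(tau, params$rm * coeffs$cm_of_t(t0)[1], na.rm = TRUE)
}

#' Integrate the membrane equation
#'
#' Numerically solves the circuit ODE with `V_m = vr` at the window start,
#' using the adaptive `lsoda` solver (relative tolerance 1e-8 by default).
#' Integration is split at the coefficient break points (pulse onset and
#' offset) so the solver never steps across a derivative discontinuity, and
#' the maximum step within each segment is one tenth of the smallest time
#' constant active there. Output is sampled on the uniform acquisition grid.
#'
#' @param coeffs A [circuit_coefficients()] object.
#' @param params A [membrane_params()].
#' @param t_span Length-2 window `(t0, t1)` in ms; must cover any light pulse
#'   plus at least 50 ms of pre-pulse baseline if metrics are to be computed.
#' @param rate Output sampling rate, kHz.
#' @param rtol,atol Solver tolerances.
#' @param vm0 Initial membrane potential, mV; defaults to the resting
#'   potential (traces start from rest / the holding potential).
#' @return A [vm_trace()] of `V_m` in mV.
#' @examples
#' mem <- membrane_params()
#' co <- build_coefficients(mem, photoswitch_params(), light_protocol())
#' tr <- simulate_vm(co, mem, t_span = c(0, 500), rate = 20)
#' @export
simulate_vm <- function(coeffs, params, t_span = c(0, 500), rate = 20,
                        rtol = 1e-8, atol = 1e-10, vm0 = params$vr) {
  stopifnot(inherits(coeffs, "circuit_coefficients"),
            inherits(params, "membrane_params"))
  stop_if_bad(
    is.numeric(t_span) && length(t_span) == 2L && t_span[2] > t_span[1],
    "t_span must be an increasing length-2 interval (ms)",
    is_num1(rate) && rate > 0, "rate must be positive (kHz)"
  )
  n <- round((t_span[2] - t_span[1]) * rate)
  grid <- t_span[1] + (0:n) / rate
  bounds <- seg_bounds(coeffs, t_span[1], t_span[2])
  rhs <- function(t, y, p) {
    cm <- coeffs$cm_of_t(t)
    list(coeffs$dvs_dt(t) -
           coeffs$dcm_dt(t) * (y[1] - coeffs$vs_of_t(t)) / cm +
           (params$vr - y[1]) / (cm * params$rm))
  }
  stop_if_bad(is_num1(vm0), "vm0 must be a single finite number (mV)")
  v <- numeric(length(grid))
  v[1] <- vm0
  y0 <- vm0
  eps <- 1e-9
  for (k in seq_len(length(bounds) - 1L)) {
    s0 <- bounds[k]; s1 <- bounds[k + 1L]
    in_seg <- which(grid > s0 + eps & grid <= s1 + eps)
    times <- unique(c(s0, grid[in_seg], s1))
    hmax <- seg_tau_at(coeffs, s0, params) / 10
    sol <- deSolve::ode(y = c(vm = y0), times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol, hmax = hmax)
    diagn <- attributes(sol)$istate
    if (!is.null(diagn) && diagn[1] < 0)
      stop("ODE solver failed in segment [", s0, ", ", s1, "] ms (istate = ",
           diagn[1], ")")
    if (any(!is.finite(sol[, "vm"])))
      stop("ODE solver produced non-finite values in segment [", s0, ", ", s1, "] ms")
    if (length(in_seg))
      v[in_seg] <- sol[match(grid[in_seg], sol[, "time"]), "vm"]
    y0 <- unname(sol[nrow(sol), "vm"])
  }
  vm_trace(grid, v, rate = rate,
           meta = list(channel = "vm_mV", source = "simulate_vm"))
}

#' Fixed-step Euler reference solution
#'
#' Brute-force explicit Euler integration at a very small fixed step
#' (1 microsecond by default), used only as an independent oracle in tests
#' against [simulate_vm()]. The step must not exceed 0.001 ms.
#'
#' @inheritParams simulate_vm
#' @param dt Euler step, ms; must be `<= 0.001` and divide the sample
#'   interval `1/rate` exactly.
#' @return A [vm_trace()] sampled at `rate`.
#' @export
euler_vm <- function(coeffs, params, t_span = c(0, 500), dt = 0.001, rate = 20,
                     vm0 = params$vr) {
  stopifnot(inherits(coeffs, "circuit_coefficients"),
            inherits(params, "membrane_params"))
  stop_if_bad(
    is.numeric(t_span) && length(t_span) == 2L && t_span[2] > t_span[1],
    "t_span must be an increasing length-2 interval (ms)",
    is_num1(dt) && dt > 0, "dt must be positive (ms)",
    is_num1(rate) && rate > 0, "rate must be positive (kHz)"
  )
  if (dt > 0.001 + 1e-15)
    stop("Euler oracle requires dt <= 0.001 ms; got ", dt)
  stride <- 1 / (rate * dt)
  if (abs(stride - round(stride)) > 1e-9)
    stop("1/rate must be an integer multiple of dt")
  stride <- round(stride)
  n <- round((t_span[2] - t_span[1]) / dt)
  tt <- t_span[1] + (0:n) * dt
  cmv <- coeffs$cm_of_t(tt)
  if (any(cmv <= 0)) stop("C_m(t) must stay positive")
  dcmv <- coeffs$dcm_dt(tt)
  vsv <- coeffs$vs_of_t(tt)
  dvsv <- coeffs$dvs_dt(tt)
  stop_if_bad(is_num1(vm0), "vm0 must be a single finite number (mV)")
  vr <- params$vr; rm <- params$rm
  vm <- numeric(n + 1L)
  vm[1L] <- vm0
  for (i in seq_len(n)) {
    d <- dvsv[i] - dcmv[i] * (vm[i] - vsv[i]) / cmv[i] +
      (vr - vm[i]) / (cmv[i] * rm)
    vm[i + 1L] <- vm[i] + dt * d
  }
  idx <- seq(1L, n + 1L, by = stride)
  vm_trace(tt[idx], vm[idx], rate = rate,
           meta = list(channel = "vm_mV", source = "euler_vm"))
}

#' Instantaneous capacitance step limit
#'
#' In the limit of a capacitance change much faster than both the kinetics
#' and the membrane time constant, the stored charge `(V_m - V_s) C_m` is
#' conserved across the step, so
#' `V_m_after = V_s + (V_m - V_s) * c_before / c_after`. Used as an analytic
#' oracle for fast capacitance transients.
#'
#' @param vm Membrane potential just before the step, mV.
#' @param vs Surface potential (constant across the step), mV.
#' @param c_before,c_after Capacitance before/after, pF; both positive.
#' @return Membrane potential just after the step, mV.
#' @examples
#' instantaneous_cap_step(-60, 0, 26.7, 22.7)  # -15 % C_m drop from rest
#' @export
instantaneous_cap_step <- function(vm, vs, c_before, c_after) {
  stop_if_bad(
    is_num1(vm), "vm must be finite (mV)",
    is_num1(vs), "vs must be finite (mV)",
    is_num1(c_before) && c_before > 0, "c_before must be positive (pF)",
    is_num1(c_after) && c_after > 0, "c_after must be positive (pF)"
  )
  vs + (vm - vs) * c_before / c_after
}

#' Constant-coefficient RC relaxation
#'
#' With constant `C_m` and `V_s` the membrane equation reduces to the bare
#' RC leak, whose closed form is
#' `V_m(t) = vr + (vm0 - vr) * exp(-t / (rm * cm0))`. Used as an analytic
#' oracle for the integrator.
#'
#' @param vm0 Initial membrane potential, mV.
#' @param params A [membrane_params()].
#' @param t Time(s) since the initial condition, ms (vectorized).
#' @return Membrane potential(s), mV.
#' @export
relaxation_closed_form <- function(vm0, params, t) {
  stopifnot(inherits(params, "membrane_params"))
  stop_if_bad(is_num1(vm0), "vm0 must be finite (mV)")
  params$vr + (vm0 - params$vr) * exp(-t / (params$rm * params$cm0))
}
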