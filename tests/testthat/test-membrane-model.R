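# The circuit ODE right-hand side, its integrators and its analytic limits.

test_that("right-hand side matches hand-evaluated cases", {
  mem <- membrane_params(cm0 = 26.7, rm = 1, vr = -60, vs0 = 0)

  # constant solution at rest: every term vanishes
  co <- constant_coefficients(26.7, 0)
  expect_equal(membrane_rhs(-60, 10, co, mem), 0)

  # capacitive term alone: -dcm/dt * (vm - vs)/cm
  co_cap <- circuit_coefficients(
    cm_of_t = function(t) rep(26.7, length(t)),
    dcm_dt = function(t) rep(-1, length(t)),
    vs_of_t = function(t) numeric(length(t)),
    dvs_dt = function(t) numeric(length(t))
  )
  mem_inf <- membrane_params(cm0 = 26.7, rm = 1e12, vr = -60, vs0 = 0)
  expect_equal(membrane_rhs(-60, 0, co_cap, mem_inf), -60 / 26.7,
               tolerance = 1e-9)

  # leak term alone: (vr - vm)/(cm rm)
  mem2 <- membrane_params(cm0 = 25, rm = 1, vr = -60, vs0 = 0)
  co2 <- constant_coefficients(25, 0)
  expect_equal(membrane_rhs(-70, 0, co2, mem2), 0.4)
})

test_that("right-hand side rejects invalid states", {
  mem <- default_mem()
  co <- constant_coefficients(25, 0)
  expect_error(membrane_rhs(NaN, 0, co, mem), "non-finite")
  bad <- circuit_coefficients(
    cm_of_t = function(t) rep(-1, length(t)),
    dcm_dt = function(t) numeric(length(t)),
    vs_of_t = function(t) numeric(length(t)),
    dvs_dt = function(t) numeric(length(t))
  )
  expect_error(membrane_rhs(-60, 0, bad, mem), "positive")
})

test_that("RC relaxation closed form is an e-folding decay", {
  mem <- membrane_params(cm0 = 25, rm = 1, vr = -60, vs0 = 0)
  expect_equal(relaxation_closed_form(-70, mem, 0), -70)
  expect_equal(relaxation_closed_form(-70, mem, 25), -60 - 10 * exp(-1),
               tolerance = 1e-9)
  expect_equal(relaxation_closed_form(-70, mem, 1e5), -60)
})

test_that("adaptive integration matches the RC closed form everywhere", {
  mem <- membrane_params(cm0 = 25, rm = 1, vr = -60, vs0 = 0)
  co <- constant_coefficients(25, 0)
  tr <- simulate_vm(co, mem, t_span = c(0, 200), rate = 20, vm0 = -70,
                    rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tr$v - relaxation_closed_form(-70, mem, tr$t))), 1e-6)
})

test_that("no light means a flat trace at rest", {
  mem <- default_mem()
  co <- constant_coefficients(mem$cm0, mem$vs0)
  tr <- simulate_vm(co, mem, t_span = c(0, 200), rate = 20)
  expect_lt(max(abs(tr$v - mem$vr)), 1e-6)
  eu <- euler_vm(co, mem, t_span = c(0, 20), dt = 0.001, rate = 20)
  expect_true(all(eu$v == mem$vr))
})

test_that("instantaneous capacitance step conserves stored charge", {
  expect_equal(instantaneous_cap_step(-60, 0, 26.7, 22.7), -60 * 26.7 / 22.7,
               tolerance = 1e-12)
  # vm == vs: no stored charge, any capacitance pair leaves vm unchanged
  for (pair in list(c(10, 20), c(26.7, 22.7), c(5, 5)))
    expect_equal(instantaneous_cap_step(-33, -33, pair[1], pair[2]), -33)
  expect_equal(instantaneous_cap_step(-60, 5, 25, 25), -60)
  expect_error(instantaneous_cap_step(-60, 0, -1, 20), "positive")
})

test_that("a fast capacitance transient approaches the charge-conservation limit", {
  mem <- default_mem()
  ps <- photoswitch_params(dcm_rel = -0.15, dvs = 0,
                           tau_on_c = 0.01, tau_off_c = 100)
  prot <- light_protocol(t_on = 50, duration = 20)
  co <- build_coefficients(mem, ps, prot)
  tr <- simulate_vm(co, mem, t_span = c(0, 80), rate = 200)
  predicted <- instantaneous_cap_step(mem$vr, mem$vs0, mem$cm0, mem$cm0 * 0.85)
  observed <- tr$v[which.min(abs(tr$t - (50 + 0.1)))]
  expect_lt(abs(observed - predicted) / abs(predicted - mem$vr), 0.01)
})

test_that("a fast surface-potential step shifts V_m by its own amplitude", {
  mem <- default_mem()
  amp <- 5
  ps <- photoswitch_params(dcm_rel = 0, dvs = amp,
                           tau_on_s = 0.01, tau_off_s = 100)
  prot <- light_protocol(t_on = 50, duration = 20)
  co <- build_coefficients(mem, ps, prot)
  tr <- simulate_vm(co, mem, t_span = c(0, 80), rate = 200)
  before <- tr$v[which.min(abs(tr$t - 49.9))]
  after <- tr$v[which.min(abs(tr$t - 50.1))]
  expect_lt(abs((after - before) - amp) / amp, 0.01)
})

test_that("Euler oracle agrees with the adaptive solver on the default pulse", {
  mem <- default_mem()
  co <- build_coefficients(mem, photoswitch_params(), light_protocol())
  a <- simulate_vm(co, mem, t_span = c(0, 150), rate = 20)
  b <- euler_vm(co, mem, t_span = c(0, 150), dt = 0.001, rate = 20)
  expect_lt(max(abs(a$v - b$v)), 0.01)
})

test_that("Euler oracle enforces its step-size precondition", {
  mem <- default_mem()
  co <- constant_coefficients(mem$cm0, mem$vs0)
  expect_error(euler_vm(co, mem, t_span = c(0, 10), dt = 0.5), "dt <= 0.001")
})

test_that("solver rejects a malformed window", {
  mem <- default_mem()
  co <- constant_coefficients(mem$cm0, mem$vs0)
  expect_error(simulate_vm(co, mem, t_span = c(10, 10)), "t_span")
})
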