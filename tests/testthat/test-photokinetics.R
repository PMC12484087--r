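# Cis-occupancy kinetics and the assembled C_m(t) / V_s(t) coefficients.

test_that("occupancy closed form has the first-order plateau and rise", {
  prot <- light_protocol(t_on = 50, duration = 500)
  occ <- cis_occupancy(prot, tau_on = 2, tau_off = 100)
  x_inf <- 100 / 102
  tau_eff <- 2 * 100 / 102

  # dark state
  expect_equal(occ$x_of_t(c(0, 49.99)), c(0, 0))
  expect_equal(occ$dx_dt(c(0, 49.99)), c(0, 0))
  # long-pulse plateau
  expect_equal(occ$x_of_t(50 + 500), x_inf * (1 - exp(-500 / tau_eff)),
               tolerance = 1e-12)
  expect_equal(occ$x_of_t(50 + 400), x_inf, tolerance = 1e-6)
  # one effective time constant into the pulse
  expect_equal(occ$x_of_t(50 + tau_eff), x_inf * (1 - exp(-1)),
               tolerance = 1e-12)
})

test_that("occupancy is bounded, monotone per phase, and continuous at the switches", {
  for (taus in list(c(2, 100), c(0.5, 30), c(10, 10), c(100, 2))) {
    prot <- light_protocol(t_on = 50, duration = 20)
    occ <- cis_occupancy(prot, taus[1], taus[2])
    t_pulse <- seq(50, 70, by = 0.01)
    t_post <- seq(70, 400, by = 0.05)
    x_pulse <- occ$x_of_t(t_pulse)
    x_post <- occ$x_of_t(t_post)
    expect_true(all(x_pulse >= 0 & x_pulse <= 1))
    expect_true(all(diff(x_pulse) >= 0))     # non-decreasing under light
    expect_true(all(diff(x_post) <= 0))      # non-increasing after light
    # value-matched at both switch instants
    expect_equal(occ$x_of_t(50 - 1e-9), 0, tolerance = 1e-7)
    expect_equal(occ$x_of_t(70 + 1e-9), occ$x_of_t(70 - 1e-9), tolerance = 1e-7)
  }
})

test_that("coefficient derivatives are the exact derivatives of their values", {
  mem <- default_mem()
  ps <- photoswitch_params()
  prot <- light_protocol(t_on = 50, duration = 20)
  co <- build_coefficients(mem, ps, prot, vs_scale = 1)
  h <- 1e-4
  # probe everywhere except within h of the two switch instants
  ts <- setdiff(seq(1, 400, by = 0.7), c(50, 70))
  ts <- ts[abs(ts - 50) > 2 * h & abs(ts - 70) > 2 * h]
  fd_cm <- (co$cm_of_t(ts + h) - co$cm_of_t(ts - h)) / (2 * h)
  fd_vs <- (co$vs_of_t(ts + h) - co$vs_of_t(ts - h)) / (2 * h)
  scale_cm <- max(abs(co$dcm_dt(ts)))
  scale_vs <- max(abs(co$dvs_dt(ts)))
  expect_lt(max(abs(fd_cm - co$dcm_dt(ts))) / scale_cm, 1e-6)
  expect_lt(max(abs(fd_vs - co$dvs_dt(ts))) / scale_vs, 1e-6)
})

test_that("coefficient plateaus reproduce the configured amplitudes", {
  mem <- membrane_params(cm0 = 26.67, vs0 = 0)
  prot <- light_protocol(t_on = 50, duration = 3000)
  t_late <- 50 + 2999

  # saturating drive (tau_on << tau_off): plateau occupancy is ~1, so the
  # full configured amplitudes appear: a 4 pF capacitance drop, a +5 mV step
  sat <- photoswitch_params(dcm_rel = -0.15, dvs = 5,
                            tau_on_c = 0.5, tau_off_c = 5000,
                            tau_on_s = 0.5, tau_off_s = 5000)
  co_sat <- build_coefficients(mem, sat, prot, vs_scale = 1)
  expect_equal(co_sat$cm_of_t(t_late), 26.67 * 0.85, tolerance = 1e-3)
  expect_equal(co_sat$vs_of_t(t_late), 5, tolerance = 1e-3)

  # generic first-order drive: plateau occupancy is tau_off/(tau_on + tau_off)
  ps <- photoswitch_params(dcm_rel = -0.15, dvs = 5)
  co <- build_coefficients(mem, ps, prot, vs_scale = 1)
  xinf_c <- ps$tau_off_c / (ps$tau_on_c + ps$tau_off_c)
  xinf_s <- ps$tau_off_s / (ps$tau_on_s + ps$tau_off_s)
  expect_equal(co$cm_of_t(t_late), 26.67 * (1 - 0.15 * xinf_c), tolerance = 1e-6)
  expect_equal(co$vs_of_t(t_late), 5 * xinf_s, tolerance = 1e-6)

  # amplitudes off -> constant baselines
  co0 <- build_coefficients(mem, photoswitch_params(dcm_rel = 0, dvs = 0), prot)
  ts <- seq(0, 500, by = 1)
  expect_true(all(co0$cm_of_t(ts) == 26.67))
  expect_true(all(co0$vs_of_t(ts) == 0))

  # field scaling multiplies only the surface-potential amplitude
  co_sc <- build_coefficients(mem, ps, prot, vs_scale = 1.4167)
  expect_equal(co_sc$vs_of_t(t_late), 5 * xinf_s * 1.4167, tolerance = 1e-6)
  expect_equal(co_sc$cm_of_t(t_late), co$cm_of_t(t_late))
})

test_that("C_m(t) continuity holds at pulse onset and offset", {
  mem <- default_mem()
  co <- build_coefficients(mem, photoswitch_params(), light_protocol())
  for (b in c(50, 70)) {
    expect_equal(co$cm_of_t(b - 1e-9), co$cm_of_t(b + 1e-9), tolerance = 1e-6)
    expect_equal(co$vs_of_t(b - 1e-9), co$vs_of_t(b + 1e-9), tolerance = 1e-6)
  }
})

test_that("invalid kinetics and amplitudes are rejected", {
  expect_error(photoswitch_params(tau_on_c = 0), "tau_on_c")
  expect_error(photoswitch_params(dcm_rel = -1), "dcm_rel")
  expect_error(cis_occupancy(light_protocol(), tau_on = -1, tau_off = 10),
               "tau_on")
})
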