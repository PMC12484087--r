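# Trace metrics, the amplitude-vs-V_r regression and parameter recovery.

test_that("metrics of a flat trace are all zero deflections", {
  prot <- light_protocol(t_on = 50, duration = 20)
  tr <- square_deflection_trace(amp = 0)
  m <- compute_metrics(tr, prot)
  expect_equal(m$baseline, -60)
  expect_equal(m$peak_deflection, 0)
  expect_equal(m$rebound_peak, 0)
  expect_equal(m$plateau, 0)
})

test_that("a known injected square deflection is measured exactly", {
  prot <- light_protocol(t_on = 50, duration = 20)
  m <- compute_metrics(square_deflection_trace(amp = -5), prot)
  expect_equal(m$peak_deflection, -5)
  expect_lte(m$time_to_peak, 25)
  m2 <- compute_metrics(square_deflection_trace(amp = 3), prot)
  expect_equal(m2$peak_deflection, 3)
})

test_that("metrics are invariant to a constant offset of the whole trace", {
  cfg <- short_cfg()
  tr <- simulate_config(cfg)
  prot <- as_light_protocol(cfg)
  m0 <- compute_metrics(tr, prot)
  shifted <- vm_trace(tr$t, tr$v + 12.34, tr$rate)
  m1 <- compute_metrics(shifted, prot)
  expect_equal(m1$baseline, m0$baseline + 12.34)
  for (f in c("peak_deflection", "time_to_peak", "rebound_peak", "plateau"))
    expect_equal(m1[[f]], m0[[f]], tolerance = 1e-9)
})

test_that("metrics enforce their coverage preconditions", {
  prot <- light_protocol(t_on = 50, duration = 20)
  short_pre <- vm_trace(seq(20, 300, by = 0.05), rep(-60, 5601), rate = 20)
  expect_error(compute_metrics(short_pre, prot), "before pulse onset")
  short_post <- vm_trace(seq(0, 150, by = 0.05), rep(-60, 3001), rate = 20)
  expect_error(compute_metrics(short_post, prot), "after pulse offset")
})

test_that("regression recovers an exact line and rejects degenerate designs", {
  vr <- c(-85, -70, -55, -40, -25)
  pts <- data.frame(vr = vr, peak = 0.1 * vr + 1)
  reg <- amplitude_vs_vr_regression(pts)
  expect_equal(reg$slope, 0.1, tolerance = 1e-12)
  expect_equal(reg$intercept, 1, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)

  # zero-slope data with noise: R^2 near zero
  set.seed(42)
  flat <- data.frame(vr = vr, peak = rnorm(5, 0, 0.1))
  reg0 <- amplitude_vs_vr_regression(flat)
  expect_lt(reg0$r_squared, 0.5)

  expect_error(amplitude_vs_vr_regression(data.frame(vr = c(-60, -60, -60),
                                                     peak = c(1, 2, 3))),
               "degenerate")
  expect_error(amplitude_vs_vr_regression(pts[1:2, ]), "3 points")
})

test_that("noise-free fit started at the truth stays at the truth", {
  cfg <- short_cfg()
  tr <- simulate_config(cfg)
  truth <- as_photoswitch_params(cfg)
  fit <- fit_photoswitch(tr, as_light_protocol(cfg), as_membrane_params(cfg),
                         init = truth, free = c("dcm_rel", "dvs"),
                         vs_scale = field_scale(as_dipole_config(cfg), -60),
                         n_starts = 1)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["dcm_rel"]), truth$dcm_rel, tolerance = 1e-4)
  expect_equal(unname(coef(fit)["dvs"]), truth$dvs, tolerance = 1e-4)
  expect_lt(fit$residual_norm, 1e-3)
})

test_that("a photoswitch-free cell fits to near-zero amplitudes", {
  cfg <- short_cfg(photoswitch = list(dcm_rel = 0, dvs_mV = 0))
  tr <- simulate_config(cfg)   # flat at rest
  fit <- fit_photoswitch(tr, as_light_protocol(cfg), as_membrane_params(cfg),
                         init = photoswitch_params(dcm_rel = -0.05, dvs = 1),
                         free = c("dcm_rel", "dvs"), n_starts = 1)
  expect_lt(abs(coef(fit)["dcm_rel"]), 1e-3)
  expect_lt(abs(coef(fit)["dvs"]), 1e-2)
})

test_that("fit object supports the standard modelling methods", {
  cfg <- short_cfg()
  syn <- generate_trace(cfg, noise_model(sigma = 0.3, seed = 3))
  fit <- fit_photoswitch(syn$trace, as_light_protocol(cfg),
                         as_membrane_params(cfg),
                         init = photoswitch_params(dcm_rel = -0.1, dvs = 3),
                         free = c("dcm_rel", "dvs"),
                         vs_scale = field_scale(as_dipole_config(cfg), -60),
                         n_starts = 1)
  expect_named(coef(fit), c("dcm_rel", "dvs"))
  expect_length(fitted(fit), length(syn$trace$v))
  expect_equal(residuals(fit), syn$trace$v - fitted(fit))
  expect_equal(sd(residuals(fit)), 0.3, tolerance = 0.15)
  s <- summary(fit)
  expect_true(all(is.finite(s$coefficients[, "Std. Error"])))
  pred <- predict(fit)
  expect_s3_class(pred, "vm_trace")
  expect_equal(pred$v, fitted(fit), tolerance = 1e-9)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$v, sims[[2]]$v))
  expect_error(fit_photoswitch(syn$trace, as_light_protocol(cfg),
                               as_membrane_params(cfg), free = "nope"),
               "free")
})
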