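#!/usr/bin/env Rscript
# Calibration of the free model constants.
#
# The reference amplitudes (dC_m = -15 % of 26.67 pF, dV_s = +5 mV), the
# pulse (20 ms, 470 nm, 50 mW/mm^2), R_m = 1 GOhm and the 20 kHz sampling
# are fixed experimental conditions. The baseline surface potential vs0
# (allowed band [0, +15] mV) and the four kinetic time constants
# (millisecond-scale rise, tens-to-hundreds-of-ms decay) are not reported
# quantities; they are calibrated ONCE by this script against three
# simultaneous constraints and then frozen in default_config():
#
#   1. dipolar cancellation of the peak deflection at vr = -60 mV close to
#      -3 mV (band +/- 1 mV);
#   2. peak hyperpolarization of a representative depolarized cell
#      (vr = -21 mV, field scaling on) close to -6 mV (band +/- 1.5 mV);
#   3. the fixed-step Euler reference (dt = 0.001 ms) must agree with the
#      adaptive solver to < 0.01 mV on the worst-case protocol trace
#      (an accuracy constraint: forward Euler's O(dt) error grows as the
#      capacitance rise constant shrinks, which bounds tau_on_c from below).
#
# The frozen point maximizes the minimum normalized margin over the three
# bands. Run from the repository root:
#   Rscript scripts/calibrate.R

library(photodipole)

delta_and_rep <- function(cfg) {
  c(delta = run_dual_pathway(cfg)$summary$delta_peak_mV,
    rep = run_representative_cell(cfg)$summary$peak_deflection_mV)
}

worst_oracle_dev <- function(cfg) {
  devs <- c()
  for (vr in c(-85, -60)) {          # the largest-transient holds
    cfg2 <- cfg
    cfg2$membrane$vr_mV <- vr
    mem <- as_membrane_params(cfg2)
    sc <- field_scale(as_dipole_config(cfg2), vr)
    for (dvs in c(cfg$photoswitch$dvs_mV * sc, 0, -cfg$photoswitch$dvs_mV * sc)) {
      ps <- as_photoswitch_params(cfg2)
      ps$dvs <- dvs
      co <- build_coefficients(mem, ps, as_light_protocol(cfg2), vs_scale = 1)
      a <- simulate_vm(co, mem, c(0, cfg$simulation$window_ms), cfg$simulation$rate_kHz)
      b <- euler_vm(co, mem, c(0, cfg$simulation$window_ms), dt = 0.001,
                    rate = cfg$simulation$rate_kHz)
      devs <- c(devs, max(abs(a$v - b$v)))
    }
  }
  max(devs)
}

grid <- expand.grid(vs0 = c(10, 12, 14, 15),
                    tau_on_c = c(0.7, 0.85, 0.9, 0.95, 1.0, 1.2),
                    tau_on_s = c(2, 3, 4, 5),
                    tau_off_s = c(20, 30, 50, 100),
                    tau_off_c = c(100))
best <- NULL
for (i in seq_len(nrow(grid))) {
  g <- grid[i, ]
  cfg <- default_config()
  cfg$membrane$vs0_mV <- g$vs0
  cfg$photoswitch$tau_on_c_ms <- g$tau_on_c
  cfg$photoswitch$tau_off_c_ms <- g$tau_off_c
  cfg$photoswitch$tau_on_s_ms <- g$tau_on_s
  cfg$photoswitch$tau_off_s_ms <- g$tau_off_s
  dr <- delta_and_rep(cfg)
  m1 <- (1 - abs(dr["delta"] + 3)) / 1
  m2 <- (1.5 - abs(dr["rep"] + 6)) / 1.5
  if (m1 < 0.1 || m2 < 0.1) next     # hopeless: skip the expensive oracle check
  dev <- worst_oracle_dev(cfg)
  m3 <- (0.01 - dev) / 0.01
  score <- min(m1, m2, m3)
  if (is.null(best) || score > best$score)
    best <- list(score = score, grid = g, delta = dr[["delta"]],
                 rep = dr[["rep"]], dev = dev)
}

cat("Frozen calibration point (max-min normalized margin):\n")
print(best$grid, row.names = FALSE)
cat(sprintf("  cancellation at -60 mV : %.3f mV (band -3 +/- 1)\n", best$delta))
cat(sprintf("  representative (-21 mV): %.3f mV (band -6 +/- 1.5)\n", best$rep))
cat(sprintf("  worst Euler-oracle dev : %.5f mV (bound 0.01)\n", best$dev))
cat(sprintf("  minimum margin         : %.1f %%\n", 100 * best$score))
cat("\nThese values are frozen in default_config() and inst/extdata/default_config.yaml.\n")
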