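# Shared fixtures. Everything is generated in code; the short window keeps
# unit tests fast while still covering the 50 ms baseline + pulse + 200 ms
# post-offset coverage the metrics need.

short_cfg <- function(...) {
  cfg <- default_config()
  cfg$simulation$window_ms <- 300
  overrides <- list(...)
  for (sec in names(overrides))
    for (k in names(overrides[[sec]]))
      cfg[[sec]][[k]] <- overrides[[sec]][[k]]
  validate_config(cfg)
  cfg
}

default_mem <- function() membrane_params()

# a trace at rest with a clean square deflection injected during the pulse
square_deflection_trace <- function(amp = -5, vr = -60, rate = 20,
                                    t_on = 50, duration = 20, t_end = 300) {
  n <- round(t_end * rate)
  t <- (0:n) / rate
  v <- rep(vr, n + 1)
  v[t >= t_on & t < t_on + duration] <- vr + amp
  vm_trace(t, v, rate)
}
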