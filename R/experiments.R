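#' Protocol runners for the reference simulation panels
#'
#' Four deterministic protocol runners reproduce the package's reference
#' simulation panels:
#' * [run_dual_pathway()] — the same cell with and without the dipolar
#'   (surface-potential) pathway, quantifying how much of the
#'   capacitance-driven hyperpolarization the dipolar depolarization
#'   cancels;
#' * [run_vr_sweep()] — the dual-pathway response across holding
#'   potentials, with the amplitude-vs-V_r regression;
#' * [run_polarity_panel()] — positive / negative / null surface-potential
#'   step at fixed capacitance drive;
#' * [run_representative_cell()] — a depolarized cell (V_r = -21 mV by
#'   default) under the full model.
#'
#' All runners return an `experiment_result`: labelled traces, matching
#' [compute_metrics()] results, and a summary list of derived numbers.
#'
#' @param cfg A `run_config` (see [default_config()], [load_config()]).
#' @return An object of class `experiment_result` with elements `traces`
#'   (named list of [vm_trace()]), `metrics` (named list of
#'   `trace_metrics`) and `summary` (named list).
#' @name experiments
NULL

experiment_result <- function(traces, metrics, summary) {
  stopifnot(identical(names(traces), names(metrics)),
            !anyDuplicated(names(traces)))
  structure(list(traces = traces, metrics = metrics, summary = summary),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment result with", length(x$traces), "trace(s):",
      paste(names(x$traces), collapse = ", "), "\n")
  for (nm in names(x$metrics)) {
    cat(sprintf("  %-10s peak %+8.3f mV at %6.2f ms, rebound %+7.3f mV\n",
                nm, x$metrics[[nm]]$peak_deflection,
                x$metrics[[nm]]$time_to_peak, x$metrics[[nm]]$rebound_peak))
  }
  cat("Summary:\n")
  for (nm in names(x$summary)) {
    val <- x$summary[[nm]]
    if (is.numeric(val) && length(val) == 1)
      cat(sprintf("  %s = %.4g\n", nm, val))
  }
  invisible(x)
}

# simulate one trace from cfg with optional overrides, returning trace+metrics
run_one <- function(cfg, vr = NULL, dvs_signed = NULL, dipole_on = TRUE,
                    field_scaling = NULL) {
  if (!is.null(vr)) cfg$membrane$vr_mV <- vr
  if (!is.null(field_scaling)) cfg$dipole$field_scaling_enabled <- field_scaling
  if (!is.null(dvs_signed)) {
    # bypass the geometry sign rule: apply this exact signed step
    mem <- as_membrane_params(cfg)
    ps <- as_photoswitch_params(cfg)
    ps$dvs <- dvs_signed
    protocol <- as_light_protocol(cfg)
    scale <- if (dvs_signed == 0) 1 else
      field_scale(as_dipole_config(cfg), mem$vr)
    co <- build_coefficients(mem, ps, protocol, vs_scale = scale)
    tr <- simulate_vm(co, mem, t_span = c(0, cfg$simulation$window_ms),
                      rate = cfg$simulation$rate_kHz,
                      rtol = cfg$simulation$rtol, atol = cfg$simulation$atol)
  } else {
    tr <- simulate_config(cfg, dipole_on = dipole_on)
  }
  list(trace = tr, metrics = compute_metrics(tr, as_light_protocol(cfg)))
}

#' @rdname experiments
#' @details `run_dual_pathway()` reports `delta_peak_mV`, the change in peak
#'   light-induced deflection attributable to the dipolar pathway, with the
#'   convention that a cancellation (smaller hyperpolarization with the
#'   dipole on) is negative:
#'   `delta_peak_mV = -(|peak_without| - |peak_with|)`.
#' @export
run_dual_pathway <- function(cfg = default_config()) {
  validate_config(cfg)
  with_d <- run_one(cfg, dipole_on = TRUE)
  without <- run_one(cfg, dipole_on = FALSE)
  delta <- -(abs(without$metrics$peak_deflection) -
               abs(with_d$metrics$peak_deflection))
  experiment_result(
    traces = list(dipole_on = with_d$trace, dipole_off = without$trace),
    metrics = list(dipole_on = with_d$metrics, dipole_off = without$metrics),
    summary = list(delta_peak_mV = delta,
                   peak_with_dipole_mV = with_d$metrics$peak_deflection,
                   peak_without_dipole_mV = without$metrics$peak_deflection)
  )
}

#' @rdname experiments
#' @param holds Holding potentials to sweep, mV.
#' @export
run_vr_sweep <- function(cfg = default_config(),
                         holds = c(-35, -45, -55, -65, -75, -85)) {
  validate_config(cfg)
  if (!length(holds)) stop("holds must be non-empty")
  runs <- lapply(holds, function(h) run_one(cfg, vr = h))
  labels <- sprintf("vr_%+d", as.integer(round(holds)))
  traces <- stats::setNames(lapply(runs, `[[`, "trace"), labels)
  metrics <- stats::setNames(lapply(runs, `[[`, "metrics"), labels)
  peaks <- vapply(metrics, `[[`, numeric(1), "peak_deflection")
  pts <- data.frame(vr = holds, peak = unname(peaks))
  reg <- if (length(holds) >= 3 && stats::sd(holds) > 0)
    amplitude_vs_vr_regression(pts) else NULL
  experiment_result(
    traces = traces, metrics = metrics,
    summary = list(holds_mV = holds, peaks_mV = unname(peaks),
                   regression = reg,
                   slope_mV_per_mV = if (!is.null(reg)) reg$slope else NA_real_,
                   regression_degenerate = is.null(reg))
  )
}

#' @rdname experiments
#' @details `run_polarity_panel()` simulates a positive, a negative and a
#'   null surface-potential step of the configured amplitude with the
#'   capacitance drive fixed; the summary orders the peak magnitudes
#'   (positive step < null < negative step when the capacitance pathway
#'   hyperpolarizes).
#' @export
run_polarity_panel <- function(cfg = default_config()) {
  validate_config(cfg)
  amp <- abs(cfg$photoswitch$dvs_mV)
  runs <- list(positive = run_one(cfg, dvs_signed = +amp),
               negative = run_one(cfg, dvs_signed = -amp),
               null = run_one(cfg, dvs_signed = 0))
  peaks <- vapply(runs, function(r) r$metrics$peak_deflection, numeric(1))
  ord <- names(sort(abs(peaks)))
  experiment_result(
    traces = lapply(runs, `[[`, "trace"),
    metrics = lapply(runs, `[[`, "metrics"),
    summary = list(peaks_mV = peaks,
                   magnitude_order = ord)
  )
}

#' @rdname experiments
#' @param vr Resting potential of the representative cell, mV.
#' @export
run_representative_cell <- function(cfg = default_config(), vr = -21) {
  cfg$membrane$vr_mV <- vr
  cfg$dipole$field_scaling_enabled <- TRUE
  validate_config(cfg)
  run <- run_one(cfg)
  experiment_result(
    traces = list(representative = run$trace),
    metrics = list(representative = run$metrics),
    summary = list(peak_deflection_mV = run$metrics$peak_deflection,
                   vr_mV = vr)
  )
}
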