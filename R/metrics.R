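#' Current-clamp trace metrics
#'
#' Quantifies a light-evoked response relative to its own pre-pulse
#' baseline, so every metric is invariant to a constant offset of the whole
#' trace:
#' * `baseline` — mean V_m over the 50 ms before pulse onset, mV;
#' * `peak_deflection` — signed extremum of largest magnitude of
#'   `V_m - baseline` in the peak window `[t_on, t_on + duration + 5]` ms
#'   (the 5 ms tail catches peaks delayed by the rise kinetics);
#' * `time_to_peak` — time of that extremum, ms after pulse onset;
#' * `rebound_peak` — signed maximum of `V_m - baseline` in the 200 ms after
#'   pulse offset (the depolarization rebound);
#' * `plateau` — mean of `V_m - baseline` over the last 50 ms of the rebound
#'   window.
#'
#' @param trace A [vm_trace()] covering at least 50 ms before `t_on` and
#'   200 ms after pulse offset.
#' @param protocol The [light_protocol()] used to record/simulate the trace.
#' @return An object of class `trace_metrics`.
#' @export
compute_metrics <- function(trace, protocol) {
  stopifnot(inherits(trace, "vm_trace"), inherits(protocol, "light_protocol"))
  t <- trace$t; v <- trace$v
  t_on <- protocol$t_on
  offset <- t_on + protocol$duration
  eps <- 1e-9
  if (t[1] > t_on - 50 + eps)
    stop("trace must cover at least 50 ms before pulse onset")
  if (t[length(t)] < offset + 200 - eps)
    stop("trace must cover at least 200 ms after pulse offset")
  base_idx <- t >= t_on - 50 - eps & t < t_on - eps
  baseline <- mean(v[base_idx])
  peak_idx <- which(t >= t_on - eps & t <= offset + 5 + eps)
  defl <- v[peak_idx] - baseline
  i <- which.max(abs(defl))
  reb_idx <- t > offset + eps & t <= offset + 200 + eps
  reb <- v[reb_idx] - baseline
  plat_idx <- t > offset + 150 + eps & t <= offset + 200 + eps
  structure(list(baseline = baseline,
                 peak_deflection = defl[i],
                 time_to_peak = t[peak_idx[i]] - t_on,
                 rebound_peak = max(reb),
                 plateau = mean(v[plat_idx]) - baseline),
            class = "trace_metrics")
}

#' @export
print.trace_metrics <- function(x, ...) {
  cat(sprintf(paste0("Trace metrics: baseline %.3f mV, peak %+.3f mV at %.2f ms, ",
                     "rebound %+.3f mV, plateau %+.3f mV\n"),
              x$baseline, x$peak_deflection, x$time_to_peak,
              x$rebound_peak, x$plateau))
  invisible(x)
}

#' @export
as.data.frame.trace_metrics <- function(x, ..., trace_id = NA_character_) {
  data.frame(trace_id = trace_id,
             baseline_mV = x$baseline,
             peak_mV = x$peak_deflection,
             t_peak_ms = x$time_to_peak,
             rebound_mV = x$rebound_peak,
             plateau_mV = x$plateau)
}

#' Export a set of trace metrics
#'
#' Writes a named list of [compute_metrics()] results as CSV (columns
#' `trace_id,baseline_mV,peak_mV,t_peak_ms,rebound_mV,plateau_mV`) or JSON.
#'
#' @param metrics Named list of `trace_metrics`.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(is.list(metrics), length(metrics) > 0)
  ids <- names(metrics) %||% as.character(seq_along(metrics))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lapply(metrics, unclass), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    rows <- do.call(rbind, Map(function(m, id) as.data.frame(m, trace_id = id),
                               metrics, ids))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Regression of response amplitude on holding potential
#'
#' Ordinary least squares of the peak light-evoked deflection on the resting
#' (holding) potential across cells or simulated holds. A positive slope
#' with hyperpolarizing (negative) deflections means the response grows in
#' magnitude as the cell is held more negative.
#'
#' @param points A data frame (or list of pairs) with columns/elements `vr`
#'   (mV) and `peak` (mV, signed peak deflection). At least 3 points with
#'   non-degenerate `vr`.
#' @return An object of class `vr_regression` with `slope` (mV per mV),
#'   `intercept` (mV), `r_squared` and the underlying [stats::lm] fit.
#' @export
amplitude_vs_vr_regression <- function(points) {
  if (!is.data.frame(points)) points <- as.data.frame(points)
  if (!all(c("vr", "peak") %in% names(points)))
    stop("points must have columns 'vr' and 'peak'")
  if (nrow(points) < 3L)
    stop("need at least 3 points for the regression")
  if (stats::sd(points$vr) == 0)
    stop("degenerate design: all vr equal")
  fit <- stats::lm(peak ~ vr, data = points)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 fit = fit),
            class = "vr_regression")
}

#' @export
print.vr_regression <- function(x, ...) {
  cat(sprintf("peak = %.4f * vr %+.4f  (R^2 = %.3f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
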