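#' Uniformly sampled membrane-potential trace
#'
#' Time series container used throughout the package: a strictly increasing
#' uniform time grid in ms with one value per sample (mV for membrane or
#' surface potential, pF for capacitance waveforms) and the sampling rate in
#' kHz. The grid spacing must equal `1/rate` to within a small relative
#' tolerance.
#'
#' @param t Time grid, ms; strictly increasing, uniform.
#' @param v Values, mV (or pF for capacitance waveforms).
#' @param rate Sampling rate, kHz.
#' @param meta Free-form list of labels (channel, protocol, source...).
#' @return An object of class `vm_trace`.
#' @export
vm_trace <- function(t, v, rate, meta = list()) {
  stopifnot(is.numeric(t), is.numeric(v), is.list(meta))
  stop_if_bad(is_num1(rate) && rate > 0, "rate must be positive (kHz)")
  if (length(t) != length(v))
    stop("t and v must have the same length")
  if (length(t) < 2L)
    stop("a trace needs at least two samples")
  if (any(!is.finite(t)) || any(!is.finite(v)))
    stop("trace contains non-finite values")
  dt <- diff(t)
  if (any(dt <= 0))
    stop("time grid must be strictly increasing")
  if (max(abs(dt - 1 / rate)) > 1e-6 / rate)
    stop("time grid is not uniform at spacing 1/rate")
  structure(list(t = as.numeric(t), v = as.numeric(v),
                 rate = rate, meta = meta),
            class = "vm_trace")
}

#' @export
print.vm_trace <- function(x, ...) {
  ch <- x$meta$channel %||% "vm_mV"
  cat(sprintf("Trace (%s): %d samples at %g kHz, t = [%g, %g] ms, range [%.3f, %.3f]\n",
              ch, length(x$t), x$rate, x$t[1], x$t[length(x$t)],
              min(x$v), max(x$v)))
  invisible(x)
}

#' @export
as.data.frame.vm_trace <- function(x, ...) {
  ch <- x$meta$channel %||% "vm_mV"
  out <- data.frame(time_ms = x$t, v = x$v)
  names(out)[2] <- ch
  out
}

#' @export
plot.vm_trace <- function(x, ..., xlab = "time (ms)",
                          ylab = x$meta$channel %||% "V_m (mV)", type = "l") {
  graphics::plot(x$t, x$v, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

trace_channels <- c("vm_mV", "cm_pF", "vs_mV")

#' Read and write trace CSV files
#'
#' The on-disk dialect is a two-column UTF-8 CSV with LF newlines, `.`
#' decimal separator and header `time_ms,vm_mV` (or `time_ms,cm_pF` /
#' `time_ms,vs_mV` for coefficient waveform dumps). Round-trips are lossless
#' to well below 1e-9 mV (values are written with 17 significant digits).
#' Malformed numeric rows are reported with their line numbers; non-uniform
#' or non-increasing time grids are rejected.
#'
#' @param path File path.
#' @param trace A [vm_trace()].
#' @return `read_trace()` returns a [vm_trace()] (rate inferred from the
#'   grid); `write_trace()` returns `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L) stop("trace file needs a header and >= 2 rows: ", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  ok <- length(header) == 2L && header[1L] == "time_ms" &&
    header[2L] %in% trace_channels
  if (!ok)
    stop("bad header ", sQuote(lines[1L]), "; expected 'time_ms,' + one of ",
         paste(trace_channels, collapse = "/"))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  nfield <- lengths(parts)
  tvals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  vvals <- suppressWarnings(as.numeric(vapply(parts, function(p) p[2L][[1L]] %||% NA_character_, "")))
  bad <- which(nfield != 2L | !is.finite(tvals) | !is.finite(vvals))
  if (length(bad))
    stop("malformed rows at line(s) ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", " in ", path)
  dt <- diff(tvals)
  if (any(dt <= 0)) stop("non-monotonic time grid in ", path)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("non-uniform time grid in ", path)
  rate <- 1 / stats::median(dt)
  vm_trace(tvals, vvals, rate = rate,
           meta = list(channel = header[2L], source = path))
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "vm_trace"))
  ch <- trace$meta$channel %||% "vm_mV"
  if (!ch %in% trace_channels) ch <- "vm_mV"
  con <- file(path, open = "wb")  # binary mode forces LF on every platform
  on.exit(close(con))
  writeLines(c(paste0("time_ms,", ch),
               paste0(sprintf("%.17g", trace$t), ",", sprintf("%.17g", trace$v))),
             con = con, sep = "\n")
  invisible(path)
}
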