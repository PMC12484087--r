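#' Generate a synthetic patch-clamp-like recording
#'
#' Simulates the dual-pathway model under the given configuration and
#' corrupts it the way a whole-cell current-clamp recording is: a linear
#' baseline drift plus additive Gaussian noise passed through a first-order
#' low-pass at 10 kHz equivalent (emulating the acquisition filter; the
#' simulated signal itself is already band-limited). The noise amplitude is
#' normalized so that `sigma` is the standard deviation *after* filtering.
#' The exact generating parameters are returned alongside the trace, so
#' recovery experiments have a known ground truth. The same seed always
#' yields a bitwise-identical trace.
#'
#' @param cfg A [default_config()]-shaped configuration (see [load_config()]).
#' @param noise A [noise_model()].
#' @return A list with `trace` (noisy [vm_trace()]), `clean` (noise-free
#'   trace) and `ground_truth` (the generating [photoswitch_params()]).
#' @export
generate_trace <- function(cfg, noise) {
  stopifnot(inherits(cfg, "run_config"), inherits(noise, "noise_model"))
  clean <- simulate_config(cfg)
  truth <- as_photoswitch_params(cfg)
  noisy <- add_recording_noise(clean, noise)
  list(trace = noisy, clean = clean, ground_truth = truth)
}

# add seeded drift + filtered Gaussian noise to a clean trace
add_recording_noise <- function(trace, noise) {
  n <- length(trace$t)
  dt <- 1 / trace$rate                        # ms
  drift <- noise$drift_rate * (trace$t - trace$t[1]) / 1000
  v <- trace$v + drift
  if (noise$sigma > 0) {
    fc <- 10                                   # kHz, single-pole corner
    tau_f <- 1 / (2 * pi * fc)                 # ms
    alpha <- dt / (tau_f + dt)
    # stationary variance of the filtered series is sigma_in^2 * alpha/(2-alpha)
    sigma_in <- noise$sigma * sqrt((2 - alpha) / alpha)
    eps <- with_seed(noise$seed, stats::rnorm(n, 0, sigma_in))
    filt <- as.numeric(stats::filter(alpha * eps, 1 - alpha,
                                     method = "recursive"))
    v <- v + filt
  }
  vm_trace(trace$t, v, trace$rate,
           meta = c(trace$meta[setdiff(names(trace$meta), "source")],
                    list(source = "synthetic",
                         sigma_mV = noise$sigma,
                         drift_mV_per_s = noise$drift_rate,
                         seed = noise$seed)))
}

#' Generate a cohort of synthetic cells
#'
#' Emulates a population of cells with resting potentials drawn uniformly in
#' `vr_range` (seeded); each cell's surface-potential amplitude follows the
#' field-scaling rule at its own resting potential, so the cohort carries a
#' built-in amplitude-vs-V_r relationship for regression and recovery tests.
#' Per-cell noise seeds are derived deterministically from `noise$seed`.
#'
#' @param cfg A run configuration (see [load_config()]).
#' @param n_cells Number of cells, >= 1.
#' @param vr_range Length-2 interval of resting potentials, mV.
#' @param noise A [noise_model()]; `noise$seed` seeds both the resting
#'   potentials and the per-cell noise.
#' @return A list of length `n_cells`; each element has `trace`, `clean`,
#'   `vr` and `ground_truth`.
#' @export
generate_cohort <- function(cfg, n_cells, vr_range = c(-85, -20), noise = noise_model()) {
  stopifnot(inherits(cfg, "run_config"), inherits(noise, "noise_model"))
  stop_if_bad(
    is_num1(n_cells) && n_cells >= 1 && n_cells == round(n_cells),
    "n_cells must be a positive integer",
    is.numeric(vr_range) && length(vr_range) == 2L && all(is.finite(vr_range)),
    "vr_range must be a finite length-2 interval (mV)"
  )
  if (vr_range[1] > vr_range[2]) stop("empty vr_range: min exceeds max")
  vrs <- with_seed(noise$seed, stats::runif(n_cells, vr_range[1], vr_range[2]))
  lapply(seq_len(n_cells), function(i) {
    cfg_i <- cfg
    cfg_i$membrane$vr_mV <- vrs[i]
    noise_i <- noise_model(sigma = noise$sigma, drift_rate = noise$drift_rate,
                           seed = noise$seed + i)
    out <- generate_trace(cfg_i, noise_i)
    list(trace = out$trace, clean = out$clean, vr = vrs[i],
         ground_truth = out$ground_truth)
  })
}
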