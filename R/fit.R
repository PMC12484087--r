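#' Fit photoswitch parameters to a recorded trace
#'
#' Recovers the light-coupled perturbation parameters of the dual-pathway
#' membrane model from a current-clamp trace by bounded nonlinear least
#' squares: the simulated membrane potential (same grid as the data) is
#' matched to the trace by minimizing the sum of squared residuals over the
#' chosen free parameters. Box constraints keep every time constant positive
#' and the capacitance positive (`1 + dcm_rel > 0`); a small multi-start
#' (jittered initial values, seeded) reduces the risk of local minima.
#' Non-convergence is reported in the returned object, never as an error.
#'
#' @param trace A [vm_trace()] of membrane potential (mV).
#' @param protocol The [light_protocol()] used for the recording.
#' @param mem [membrane_params()] of the cell (held fixed).
#' @param init [photoswitch_params()] starting values; fixed parameters keep
#'   these values.
#' @param free Character vector of parameters to fit, a subset of
#'   `c("dcm_rel", "dvs", "tau_on_c", "tau_off_c", "tau_on_s", "tau_off_s")`.
#' @param vs_scale Field-scaling multiplier applied to `dvs` during
#'   simulation (see [field_scale()]); 1 disables scaling.
#' @param n_starts Number of optimizer starts (first start is `init`).
#' @param seed Seed for the start jitter.
#' @param rtol,atol Solver tolerances passed to [simulate_vm()].
#' @return An object of class `photoswitch_fit` with methods [print()],
#'   [summary()], [coef()], [predict()], [fitted()], [residuals()],
#'   [plot()] and [simulate()].
#' @examples
#' \donttest{
#' cfg <- default_config()
#' syn <- generate_trace(cfg, noise_model(sigma = 0.3, seed = 1))
#' fit <- fit_photoswitch(syn$trace, as_light_protocol(cfg),
#'                        as_membrane_params(cfg))
#' coef(fit)
#' }
#' @export
fit_photoswitch <- function(trace, protocol, mem,
                            init = photoswitch_params(),
                            free = c("dcm_rel", "dvs"),
                            vs_scale = 1, n_starts = 3, seed = 1,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(trace, "vm_trace"), inherits(protocol, "light_protocol"),
            inherits(mem, "membrane_params"), inherits(init, "photoswitch_params"))
  all_free <- c("dcm_rel", "dvs", "tau_on_c", "tau_off_c", "tau_on_s", "tau_off_s")
  free <- unique(as.character(free))
  if (!length(free) || !all(free %in% all_free))
    stop("free must be a non-empty subset of: ", paste(all_free, collapse = ", "))
  lower_all <- c(dcm_rel = -0.95, dvs = -Inf, tau_on_c = 1e-3, tau_off_c = 1e-3,
                 tau_on_s = 1e-3, tau_off_s = 1e-3)
  upper_all <- c(dcm_rel = 5, dvs = Inf, tau_on_c = 1e4, tau_off_c = 1e4,
                 tau_on_s = 1e4, tau_off_s = 1e4)
  t_span <- range(trace$t)

  make_ps <- function(par) {
    vals <- unclass(init)
    vals[free] <- as.list(pmin(pmax(par, lower_all[free]), upper_all[free]))
    do.call(photoswitch_params, vals)
  }
  resid_fn <- function(par) {
    ps <- make_ps(par)
    co <- build_coefficients(mem, ps, protocol, vs_scale = vs_scale)
    sim <- simulate_vm(co, mem, t_span = t_span, rate = trace$rate,
                       rtol = rtol, atol = atol)
    trace$v - sim$v
  }

  p0 <- unlist(unclass(init)[free])
  starts <- list(p0)
  if (n_starts > 1) {
    starts <- c(starts, with_seed(seed, lapply(seq_len(n_starts - 1), function(i) {
      p <- p0
      for (nm in free) {
        p[nm] <- if (startsWith(nm, "tau")) {
          p[nm] * exp(stats::rnorm(1, 0, 0.2))
        } else if (nm == "dcm_rel") {
          p[nm] + stats::rnorm(1, 0, 0.05)
        } else {
          p[nm] + stats::rnorm(1, 0, 1)
        }
      }
      pmin(pmax(p, lower_all[free] + 1e-6), upper_all[free])
    })))
  }

  best <- NULL
  for (p in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = p, lower = lower_all[free], upper = upper_all[free],
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop("all optimizer starts failed before producing a candidate fit")

  est <- stats::setNames(as.numeric(best$par), free)
  ps_hat <- make_ps(est)
  co_hat <- build_coefficients(mem, ps_hat, protocol, vs_scale = vs_scale)
  sim_hat <- simulate_vm(co_hat, mem, t_span = t_span, rate = trace$rate,
                         rtol = rtol, atol = atol)
  df_resid <- length(trace$v) - length(free)
  sigma2 <- best$deviance / max(df_resid, 1)
  vcov_hat <- tryCatch(sigma2 * solve(best$hessian), error = function(e) NULL)

  structure(list(estimates = est,
                 params = ps_hat,
                 free = free,
                 membrane = mem,
                 protocol = protocol,
                 vs_scale = vs_scale,
                 trace = trace,
                 fitted_values = sim_hat$v,
                 ssr = best$deviance,
                 residual_norm = sqrt(best$deviance),
                 sigma = sqrt(sigma2),
                 df_residual = df_resid,
                 vcov = vcov_hat,
                 converged = best$info %in% 1:4,
                 optim_info = best$info,
                 optim_message = best$message,
                 n_starts = length(starts),
                 call = match.call()),
            class = "photoswitch_fit")
}

#' @export
print.photoswitch_fit <- function(x, ...) {
  cat("Dual-pathway photoswitch fit (bounded nonlinear least squares)\n")
  cat("Free parameters:\n")
  print(signif(x$estimates, 6))
  cat(sprintf("Residual norm: %.4g mV (sigma = %.4g mV, %d residual df)\n",
              x$residual_norm, x$sigma, x$df_residual))
  if (!x$converged)
    cat("WARNING: optimizer did not converge (", x$optim_message, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.photoswitch_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(pmax(diag(object$vcov), 0)) else
    rep(NA_real_, length(object$estimates))
  tab <- cbind(Estimate = object$estimates, `Std. Error` = se)
  out <- list(coefficients = tab, sigma = object$sigma,
              residual_norm = object$residual_norm,
              df_residual = object$df_residual,
              converged = object$converged, message = object$optim_message)
  class(out) <- "summary.photoswitch_fit"
  out
}

#' @export
print.summary.photoswitch_fit <- function(x, ...) {
  cat("Dual-pathway photoswitch fit\n\nCoefficients:\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("\nResidual sigma: %.4g mV on %d degrees of freedom\n",
              x$sigma, x$df_residual))
  cat("Converged:", x$converged, "\n")
  invisible(x)
}

#' @export
coef.photoswitch_fit <- function(object, ...) object$estimates

#' @export
fitted.photoswitch_fit <- function(object, ...) object$fitted_values

#' @export
residuals.photoswitch_fit <- function(object, ...) {
  object$trace$v - object$fitted_values
}

#' @export
vcov.photoswitch_fit <- function(object, ...) object$vcov

#' Predict the membrane-potential response of a fitted model
#'
#' Simulates the fitted dual-pathway model, by default on the grid and under
#' the protocol of the training trace; a different [light_protocol()] can be
#' supplied to predict the response to a new stimulus.
#'
#' @param object A [fit_photoswitch()] result.
#' @param protocol Optional new [light_protocol()].
#' @param t_span,rate Optional new window (ms) and sampling rate (kHz).
#' @param ... Unused.
#' @return A [vm_trace()].
#' @export
predict.photoswitch_fit <- function(object, protocol = NULL,
                                    t_span = NULL, rate = NULL, ...) {
  protocol <- protocol %||% object$protocol
  t_span <- t_span %||% range(object$trace$t)
  rate <- rate %||% object$trace$rate
  co <- build_coefficients(object$membrane, object$params, protocol,
                           vs_scale = object$vs_scale)
  simulate_vm(co, object$membrane, t_span = t_span, rate = rate)
}

#' @export
plot.photoswitch_fit <- function(x, ...) {
  graphics::plot(x$trace$t, x$trace$v, type = "l", col = "grey60",
                 xlab = "time (ms)", ylab = "V_m (mV)", ...)
  graphics::lines(x$trace$t, x$fitted_values, col = "firebrick", lwd = 2)
  graphics::legend("bottomright", legend = c("data", "fit"),
                   col = c("grey60", "firebrick"), lwd = c(1, 2), bty = "n")
  invisible(x)
}

#' Simulate new noisy traces from a fitted model
#'
#' Draws `nsim` synthetic recordings from the fitted dual-pathway model,
#' using the residual standard deviation of the fit as the recording noise
#' level (filtered additive Gaussian noise, as in [generate_trace()]).
#'
#' @param object A [fit_photoswitch()] result.
#' @param nsim Number of traces.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of [vm_trace()] objects.
#' @export
simulate.photoswitch_fit <- function(object, nsim = 1, seed = 1, ...) {
  clean <- vm_trace(object$trace$t, object$fitted_values, object$trace$rate,
                    meta = list(channel = "vm_mV", source = "fit"))
  lapply(seq_len(nsim), function(i) {
    add_recording_noise(clean,
                        noise_model(sigma = object$sigma, drift_rate = 0,
                                    seed = seed + i - 1L))
  })
}

# evaluate expr-producing function under a temporary seed, restoring RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
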