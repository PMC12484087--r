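#' The package's default (calibrated) configuration
#'
#' Nested named list holding every model, protocol and simulation setting,
#' in the package's fixed unit system (mV / pF / GOhm / ms; rates in kHz).
#' The capacitance amplitude (-15\% of 26.67 pF, i.e. a 4 pF drop), the
#' surface-potential amplitude (+5 mV), the 20 ms / 470 nm / 50 mW/mm^2
#' pulse and the 20 kHz sampling are the reference experimental conditions;
#' the baseline surface potential and the four kinetic time constants are
#' the package's calibrated defaults (see `scripts/calibrate.R` and the
#' methods vignette).
#'
#' @return An object of class `run_config` (a nested list).
#' @export
default_config <- function() {
  structure(list(
    membrane = list(cm0_pF = 26.67, rm_GOhm = 1.0, vr_mV = -60, vs0_mV = 15),
    photoswitch = list(dcm_rel = -0.15, dvs_mV = 5,
                       tau_on_c_ms = 0.9, tau_off_c_ms = 100,
                       tau_on_s_ms = 4, tau_off_s_ms = 30),
    dipole = list(mu_trans_D = 1.05, mu_cis_D = 7.35,
                  leaflet = "outer", orientation = "away_from_core",
                  coupling_mV_per_D = 1.25,
                  field_scaling_enabled = TRUE, vref_mV = -60),
    protocol = list(t_on_ms = 50, duration_ms = 20,
                    wavelength_nm = 470, irradiance_mW_mm2 = 50),
    simulation = list(window_ms = 500, rate_kHz = 20,
                      rtol = 1e-8, atol = 1e-10)
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, fills every missing key from
#' [default_config()], rejects unknown keys, and validates the physical
#' invariants by constructing the typed parameter objects. All violations
#' are collected and reported together, each naming the offending field.
#'
#' @param path Path to a YAML or JSON file (YAML is a superset of JSON, so
#'   both parse through the same reader).
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(raw)) stop("config must be a mapping of sections")
  merge_config(raw, source = path)
}

#' @rdname load_config
#' @param overrides Nested list of settings layered on top of the defaults
#'   (same shape as the file contents).
#' @param source Label used in validation error messages.
#' @export
merge_config <- function(overrides = list(), source = "<overrides>") {
  def <- unclass(default_config())
  errs <- character(0)
  unknown_sections <- setdiff(names(overrides), names(def))
  if (length(unknown_sections))
    errs <- c(errs, paste0("unknown section(s): ",
                           paste(unknown_sections, collapse = ", ")))
  for (sec in intersect(names(overrides), names(def))) {
    ov <- overrides[[sec]]
    if (!is.list(ov)) {
      errs <- c(errs, paste0("section '", sec, "' must be a mapping"))
      next
    }
    unknown <- setdiff(names(ov), names(def[[sec]]))
    if (length(unknown))
      errs <- c(errs, paste0("unknown key(s) in '", sec, "': ",
                             paste(unknown, collapse = ", ")))
    for (k in intersect(names(ov), names(def[[sec]])))
      def[[sec]][[k]] <- ov[[k]]
  }
  if (length(errs))
    stop("invalid configuration (", source, "):\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  cfg <- structure(def, class = "run_config")
  validate_config(cfg, source = source)
  cfg
}

# construct every typed object, collecting the validation messages
validate_config <- function(cfg, source = "<config>") {
  errs <- character(0)
  try_build <- function(what, expr) {
    tryCatch({ force(expr); NULL },
             error = function(e) paste0(what, ": ", conditionMessage(e)))
  }
  errs <- c(errs,
            try_build("membrane", as_membrane_params(cfg)),
            try_build("photoswitch", as_photoswitch_params(cfg)),
            try_build("dipole", as_dipole_config(cfg)),
            try_build("protocol", as_light_protocol(cfg)))
  sim <- cfg$simulation
  if (!(is_num1(sim$window_ms) && sim$window_ms > 0))
    errs <- c(errs, "simulation: window_ms must be positive")
  if (!(is_num1(sim$rate_kHz) && sim$rate_kHz > 0))
    errs <- c(errs, "simulation: rate_kHz must be positive")
  if (!(is_num1(sim$rtol) && sim$rtol > 0 && is_num1(sim$atol) && sim$atol > 0))
    errs <- c(errs, "simulation: rtol and atol must be positive")
  if (is_num1(cfg$protocol$t_on_ms) && cfg$protocol$t_on_ms < 50)
    errs <- c(errs, "protocol: t_on_ms must allow >= 50 ms of baseline")
  if (is_num1(cfg$protocol$t_on_ms) && is_num1(cfg$protocol$duration_ms) &&
      is_num1(sim$window_ms) &&
      cfg$protocol$t_on_ms + cfg$protocol$duration_ms + 200 > sim$window_ms)
    errs <- c(errs, "simulation: window_ms must cover the pulse plus 200 ms")
  errs <- errs[!vapply(errs, is.null, logical(1))]
  if (length(errs))
    stop("invalid configuration (", source, "):\n  - ",
         paste(unlist(errs), collapse = "\n  - "), call. = FALSE)
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  utils::str(unclass(x), no.list = TRUE, give.attr = FALSE)
  invisible(x)
}

#' Typed views of a run configuration
#'
#' Convert the relevant section of a `run_config` into the corresponding
#' parameter object.
#'
#' @param cfg A `run_config`.
#' @return [membrane_params()], [photoswitch_params()], [light_protocol()]
#'   or [dipole_config()] respectively.
#' @export
as_membrane_params <- function(cfg) {
  m <- cfg$membrane
  membrane_params(cm0 = m$cm0_pF, rm = m$rm_GOhm, vr = m$vr_mV, vs0 = m$vs0_mV)
}

#' @rdname as_membrane_params
#' @export
as_photoswitch_params <- function(cfg) {
  p <- cfg$photoswitch
  photoswitch_params(dcm_rel = p$dcm_rel, dvs = p$dvs_mV,
                     tau_on_c = p$tau_on_c_ms, tau_off_c = p$tau_off_c_ms,
                     tau_on_s = p$tau_on_s_ms, tau_off_s = p$tau_off_s_ms)
}

#' @rdname as_membrane_params
#' @export
as_light_protocol <- function(cfg) {
  p <- cfg$protocol
  light_protocol(t_on = p$t_on_ms, duration = p$duration_ms,
                 wavelength = p$wavelength_nm, irradiance = p$irradiance_mW_mm2)
}

#' @rdname as_membrane_params
#' @export
as_dipole_config <- function(cfg) {
  d <- cfg$dipole
  dipole_config(mu_trans = d$mu_trans_D, mu_cis = d$mu_cis_D,
                leaflet = d$leaflet, orientation = d$orientation,
                coupling_mV_per_D = d$coupling_mV_per_D,
                field_scaling_enabled = d$field_scaling_enabled,
                vref = d$vref_mV)
}

#' Simulate the membrane response for a full configuration
#'
#' Convenience wrapper: builds the coefficient functions from the
#' configuration (applying the field-scaling rule at the configured resting
#' potential, and the dipole sign rule to orient the surface-potential
#' step) and integrates the membrane equation over the configured window.
#'
#' The applied surface-potential step is
#' `|dvs_mV| * vs_step_sign(dipole) * field_scale(dipole, vr_mV)`: the
#' configured amplitude carries the magnitude, the leaflet/orientation
#' geometry carries the polarity, and the field-scaling rule modulates the
#' amplitude with the holding potential.
#'
#' @param cfg A `run_config`.
#' @param dipole_on If `FALSE`, the surface-potential pathway is switched
#'   off (`dvs = 0`): the purely opto-mechanical model.
#' @return A [vm_trace()].
#' @export
simulate_config <- function(cfg, dipole_on = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  mem <- as_membrane_params(cfg)
  ps <- as_photoswitch_params(cfg)
  protocol <- as_light_protocol(cfg)
  dip <- as_dipole_config(cfg)
  if (dipole_on) {
    sgn <- vs_step_sign(dip)
    # dvs_mV is an unsigned-in-spirit amplitude; the dipole geometry sets the sign
    ps$dvs <- if (sgn == 0) 0 else abs(ps$dvs) * sgn
    scale <- field_scale(dip, mem$vr)
  } else {
    ps$dvs <- 0
    scale <- 1
  }
  co <- build_coefficients(mem, ps, protocol, vs_scale = scale)
  simulate_vm(co, mem, t_span = c(0, cfg$simulation$window_ms),
              rate = cfg$simulation$rate_kHz,
              rtol = cfg$simulation$rtol, atol = cfg$simulation$atol)
}
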