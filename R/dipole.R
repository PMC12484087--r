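#' Molecular dipole configuration of the photoswitch
#'
#' Describes the isomerization-induced dipole change and where/how the
#' photoswitch sits in the bilayer, which together set the polarity of the
#' light-induced surface-potential step. Orientation is encoded relative to
#' the bilayer midplane (`away_from_core` means the positive end of the
#' dipole points from the midplane towards the nearest aqueous interface),
#' not in the lab frame: with this convention a single product rule covers
#' both an outer-leaflet switch with outward-pointing dipoles and an
#' inner-leaflet switch with cytosol-pointing dipoles.
#'
#' Defaults describe an amphiphilic azobenzene enriched in the outer leaflet
#' whose dipole moment grows by ~6.3 D on trans-to-cis isomerization.
#'
#' @param mu_trans,mu_cis Dipole moments of the trans and cis isomers, Debye
#'   (non-negative).
#' @param leaflet Which leaflet is enriched: `"outer"` or `"inner"`.
#' @param orientation Direction of the dipole's positive end relative to the
#'   bilayer midplane at its leaflet: `"away_from_core"` or `"toward_core"`.
#' @param coupling_mV_per_D Optional linear coupling from |dipole change| to
#'   surface-potential amplitude, mV/Debye. `NULL` disables the helper.
#' @param field_scaling_enabled If `TRUE`, the surface-potential amplitude is
#'   scaled linearly with the transmembrane field, proxied by the holding
#'   potential (see [field_scale()]).
#' @param vref Reference holding potential for field scaling, mV (non-zero).
#' @return An object of class `dipole_config`.
#' @seealso [vs_step_sign()], [vs_step_amplitude()], [field_scale()]
#' @export
dipole_config <- function(mu_trans = 1.05, mu_cis = 7.35,
                          leaflet = c("outer", "inner"),
                          orientation = c("away_from_core", "toward_core"),
                          coupling_mV_per_D = 1.25,
                          field_scaling_enabled = TRUE,
                          vref = -60) {
  leaflet <- match.arg(leaflet)
  orientation <- match.arg(orientation)
  stop_if_bad(
    is_num1(mu_trans) && mu_trans >= 0, "mu_trans must be non-negative (Debye)",
    is_num1(mu_cis) && mu_cis >= 0, "mu_cis must be non-negative (Debye)",
    is.null(coupling_mV_per_D) || (is_num1(coupling_mV_per_D) && coupling_mV_per_D >= 0),
    "coupling_mV_per_D must be NULL or a non-negative number",
    isTRUE(field_scaling_enabled) || isFALSE(field_scaling_enabled),
    "field_scaling_enabled must be TRUE or FALSE",
    is_num1(vref) && vref != 0, "vref must be a single non-zero number (mV)"
  )
  structure(list(mu_trans = mu_trans, mu_cis = mu_cis,
                 leaflet = leaflet, orientation = orientation,
                 coupling_mV_per_D = coupling_mV_per_D,
                 field_scaling_enabled = field_scaling_enabled,
                 vref = vref),
            class = "dipole_config")
}

#' @export
print.dipole_config <- function(x, ...) {
  cat("Dipole configuration:\n")
  cat(sprintf("  mu(trans) = %g D -> mu(cis) = %g D (delta = %+g D)\n",
              x$mu_trans, x$mu_cis, x$mu_cis - x$mu_trans))
  cat(sprintf("  leaflet = %s, orientation = %s\n", x$leaflet, x$orientation))
  cat(sprintf("  field scaling: %s (vref = %g mV)\n",
              if (x$field_scaling_enabled) "enabled" else "disabled", x$vref))
  invisible(x)
}

#' Polarity of the light-induced surface-potential step
#'
#' The polarity is not set by the sign of the dipole change alone: it is the
#' product of which leaflet hosts the switch, how the dipole projects onto
#' the membrane normal, and whether the dipole grows or shrinks on
#' isomerization. The rule implemented is
#' `s = s_leaflet * s_orientation * sign(mu_cis - mu_trans)` with
#' `s_leaflet = +1` (outer) / `-1` (inner) and `s_orientation = +1`
#' (away_from_core) / `-1` (toward_core). `+1` means depolarizing (raises
#' the surface potential as seen by the membrane interior). This is the
#' minimal product rule consistent with the known reference cases (an
#' outer-leaflet switch with outward dipoles and a dipole increase, and an
#' inner-leaflet switch with inward dipoles and a dipole decrease, both
#' depolarizing); it is a convention, not a derivation from double-layer
#' theory.
#'
#' @param cfg A [dipole_config()].
#' @return `+1`, `-1` or `0` (no dipole change).
#' @export
vs_step_sign <- function(cfg) {
  stopifnot(inherits(cfg, "dipole_config"))
  s_leaflet <- if (cfg$leaflet == "outer") 1 else -1
  s_orient <- if (cfg$orientation == "away_from_core") 1 else -1
  s_leaflet * s_orient * sign(cfg$mu_cis - cfg$mu_trans)
}

#' Unsigned surface-potential step amplitude from the dipole change
#'
#' Linear helper `|dvs| = coupling_mV_per_D * |mu_cis - mu_trans|`,
#' calibrated on the reference case 4 D -> 5 mV (1.25 mV/D). Protocols may
#' instead set the amplitude directly in [photoswitch_params()]; the default
#' configuration does, because the calibrated amplitude for the reference
#' azobenzene is 5 mV despite a dipole change above 6 D.
#'
#' @param cfg A [dipole_config()] with `coupling_mV_per_D` set.
#' @return Unsigned amplitude, mV.
#' @export
vs_step_amplitude <- function(cfg) {
  stopifnot(inherits(cfg, "dipole_config"))
  if (is.null(cfg$coupling_mV_per_D))
    stop("coupling_mV_per_D is not set in this dipole_config")
  cfg$coupling_mV_per_D * abs(cfg$mu_cis - cfg$mu_trans)
}

#' Field-strength scaling of the surface-potential amplitude
#'
#' Stronger transmembrane fields align the molecular dipoles more
#' effectively and amplify the surface-potential response. The field is
#' proxied by the pre-pulse holding potential; the scaling is linear in
#' `v_hold / vref`, equals 1 at the reference potential, and is clipped at 0
#' (a field of the opposite sign cannot anti-align beyond zero response in
#' this first-order picture).
#'
#' @param cfg A [dipole_config()].
#' @param v_hold Holding (resting) potential of the cell, mV.
#' @return Dimensionless non-negative multiplier; 1 when scaling is disabled.
#' @export
field_scale <- function(cfg, v_hold) {
  stopifnot(inherits(cfg, "dipole_config"))
  stop_if_bad(is_num1(v_hold), "v_hold must be a single finite number (mV)")
  if (!cfg$field_scaling_enabled) return(1)
  max(v_hold / cfg$vref, 0)
}
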