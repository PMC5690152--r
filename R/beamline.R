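# Beamline configurations for the four commissioning / clinical conditions.

#' Beamline configuration
#'
#' One deliverable field: energy, SOBP width, range-shifter thickness,
#' collimator distance, the aperture and (optionally) the compensator, the
#' phantom material, and where the dose is evaluated.
#'
#' The measurement point is on the beam axis at the isocenter (z = 0); the
#' phantom entrance is placed so that the isocenter sits at
#' `measurement_depth` (physical mm) inside the phantom. By default that
#' depth is the SOBP-center depth `(range - sobp/2 - rs) / welr`; for
#' patient-specific (PSD) fields a different depth may be supplied.
#'
#' The `"STD"` label is reserved for the exact standard condition: 190 MeV,
#' 80 mm SOBP, 0 mm RS, 300 mm collimator distance, 185 mm square aperture
#' and no compensator.
#'
#' @param energy Beam energy, MeV (150, 190 or 235).
#' @param sobp_width SOBP width, mm WEL.
#' @param rs_thickness Range-shifter thickness, mm WEL, between 0 and 120.
#' @param collimator_to_axis Collimator-to-axis distance, mm.
#' @param aperture An [aperture_collimator()].
#' @param compensator A [range_compensator()] or `NULL`.
#' @param condition_label One of `"STD"`, `"BSD"`, `"PSD"`, `"FS"`.
#' @param phantom_welr Water-equivalent thickness ratio of the phantom.
#' @param measurement_depth Physical depth of the measurement point, mm, or
#'   `NULL` for the SOBP-center depth.
#' @param measurement_lateral Lateral (x, y) of the measurement point, mm.
#' @param const A [beam_constants()] object (range-energy convention).
#' @return An object of class `beamline_config`.
#' @export
beamline_config <- function(energy, sobp_width, rs_thickness = 0,
                            collimator_to_axis = 300,
                            aperture = square_aperture(185),
                            compensator = NULL,
                            condition_label = c("BSD", "STD", "PSD", "FS"),
                            phantom_welr = 1.0,
                            measurement_depth = NULL,
                            measurement_lateral = c(0, 0),
                            const = beam_constants()) {
  condition_label <- match.arg(condition_label)
  if (!energy %in% BEAM_ENERGIES) {
    stop("energy must be one of ", paste(BEAM_ENERGIES, collapse = ", "), call. = FALSE)
  }
  if (!sobp_width %in% SOBP_WIDTHS) {
    stop("SOBP width must be on the 30..100 mm by 10 mm grid", call. = FALSE)
  }
  rs <- range_shifter(rs_thickness)   # validates [0, 120]
  stopifnot(inherits(aperture, "aperture_collimator"), collimator_to_axis > 0)
  if (!is.null(compensator)) stopifnot(inherits(compensator, "range_compensator"))
  if (condition_label == "STD") {
    ok <- energy == 190 && sobp_width == 80 && rs_thickness == 0 &&
      collimator_to_axis == 300 && is.null(compensator) &&
      isTRUE(all.equal(mean_aperture_radius(aperture), square_mean_radius(185),
                       tolerance = 1e-3))
    if (!ok) stop("STD condition must match the standard beam exactly (190 MeV, 80 mm SOBP, 0 mm RS, 300 mm, 185 mm square, no compensator)",
                  call. = FALSE)
  }
  R <- range_from_energy(energy, const)
  if (is.null(measurement_depth)) {
    measurement_depth <- phantom_depth_for_sobp_center(R, sobp_width,
                                                       rs_thickness, phantom_welr)
  }
  stopifnot(measurement_depth > 0)
  structure(list(energy = energy, sobp_width = sobp_width,
                 rs_thickness = rs_thickness,
                 collimator_to_axis = collimator_to_axis,
                 aperture = aperture, compensator = compensator,
                 condition_label = condition_label,
                 phantom_welr = phantom_welr,
                 measurement_depth = measurement_depth,
                 measurement_lateral = measurement_lateral,
                 range = R, const = const),
            class = "beamline_config")
}

#' @export
print.beamline_config <- function(x, ...) {
  cat(sprintf("<beamline_config %s: %g MeV, SOBP %g mm, RS %g mm, depth %.1f mm%s>\n",
              x$condition_label, x$energy, x$sobp_width, x$rs_thickness,
              x$measurement_depth,
              if (is.null(x$compensator)) "" else ", compensator"))
  invisible(x)
}

#' Standard and commissioning condition constructors
#'
#' `std_config()` is the standard reference beam; `bsd_config()` keeps the
#' standard collimator and no compensator but patient-specific beam
#' spreading (energy, SOBP, RS); `fs_config()` is the field-size series
#' (0 mm RS, 80 mm SOBP, square aperture of side `side`).
#'
#' @param energy,sobp_width,rs_thickness Beam-spreading parameters.
#' @param side Square aperture side, mm.
#' @param ... Passed to [beamline_config()].
#' @return A [beamline_config()].
#' @export
std_config <- function(...) {
  beamline_config(190, 80, 0, condition_label = "STD", ...)
}

#' @rdname std_config
#' @export
bsd_config <- function(energy, sobp_width, rs_thickness, ...) {
  beamline_config(energy, sobp_width, rs_thickness,
                  condition_label = "BSD", ...)
}

#' @rdname std_config
#' @export
fs_config <- function(energy, side, ...) {
  beamline_config(energy, 80, 0, aperture = square_aperture(side),
                  condition_label = "FS", ...)
}
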