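# Physical constants and beamline configuration defaults.

#' Beam model constants
#'
#' Bundles the constants used by the range-energy conversion, the analytic
#' pristine Bragg curve and the Highland scattering model.
#'
#' * `alpha`, `p`: Bragg-Kleeman power-law constants for the range of protons
#'   in water, `R = alpha * E^p` with `R` in mm and `E` in MeV. The defaults
#'   (`alpha = 0.022` mm/MeV^p, `p = 1.77`) are the widely used water values.
#' * `x0_water`: radiation length of water in mm (360.8 mm).
#' * `proton_mass`: proton rest energy in MeV.
#' * `straggling_a`, `straggling_b`: range-straggling width parameterization
#'   `sigma = straggling_a * R_cm^straggling_b` (cm), applied as a Gaussian
#'   smearing of the stopping-power peak.
#'
#' @param alpha Bragg-Kleeman coefficient, mm MeV^-p.
#' @param p Bragg-Kleeman exponent.
#' @param x0_water Radiation length of water, mm.
#' @param proton_mass Proton rest energy, MeV.
#' @param straggling_a,straggling_b Range-straggling parameterization (cm units).
#' @param energy_spread Fractional beam energy spread (1 sigma); widens the
#'   pristine peak by `p * R * energy_spread` in range while keeping the
#'   peak within a few mm of the nominal range.
#' @return A list of class `beam_constants`.
#' @export
#' @examples
#' bc <- beam_constants()
#' bc$alpha
beam_constants <- function(alpha = 0.022, p = 1.77, x0_water = 360.8,
                           proton_mass = 938.272,
                           straggling_a = 0.012, straggling_b = 0.935,
                           energy_spread = 0.008) {
  stopifnot(alpha > 0, p > 1, x0_water > 0, proton_mass > 0, energy_spread >= 0)
  structure(list(alpha = as.numeric(alpha), p = as.numeric(p),
                 x0_water = as.numeric(x0_water),
                 proton_mass = as.numeric(proton_mass),
                 straggling_a = as.numeric(straggling_a),
                 straggling_b = as.numeric(straggling_b),
                 energy_spread = as.numeric(energy_spread)),
            class = "beam_constants")
}

# Energies deliverable by the beamline (MeV) and the SOBP width grid (mm WEL).
BEAM_ENERGIES <- c(150, 190, 235)
SOBP_WIDTHS <- seq(30, 100, by = 10)

# Square aperture sides (mm) of the field-size commissioning series.
FS_APERTURE_SIDES <- c(40, 50, 70, 100, 185)

# Mean distance from the center of a square to its perimeter, per unit
# half-side: (sqrt(2) + asinh(1)) / 2.
SQUARE_MEAN_RADIUS_COEF <- (sqrt(2) + log(1 + sqrt(2))) / 2

#' Mean aperture radius of a centered square opening
#'
#' Closed form for the mean distance from the center of an `side x side`
#' square to its perimeter, used to index the field-size tables by mean
#' aperture radius.
#'
#' @param side Square side length, mm.
#' @return Mean center-to-perimeter distance, mm.
#' @export
#' @examples
#' square_mean_radius(185)
square_mean_radius <- function(side) {
  stopifnot(is.numeric(side), all(side > 0))
  SQUARE_MEAN_RADIUS_COEF * side / 2
}
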