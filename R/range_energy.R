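# Range-energy conversion and water-equivalent scaling.

#' Proton range in water from beam energy
#'
#' Bragg-Kleeman power law `R = alpha * E^p` (mm of water). The constants are
#' carried in a [beam_constants()] object so the whole package shares one
#' range-energy convention.
#'
#' @param energy Proton kinetic energy, MeV. Must lie in (50, 300).
#' @param const A [beam_constants()] object.
#' @return Range in mm of water (vectorized over `energy`).
#' @export
#' @examples
#' range_from_energy(190)
range_from_energy <- function(energy, const = beam_constants()) {
  stopifnot(is.numeric(energy))
  if (any(energy <= 50 | energy >= 300)) {
    stop("energy must be in (50, 300) MeV", call. = FALSE)
  }
  const$alpha * energy^const$p
}

#' Beam energy from proton range in water
#'
#' Inverse of [range_from_energy()]: `E = (R / alpha)^(1/p)`.
#'
#' @param range_mm Range in mm of water, > 0.
#' @param const A [beam_constants()] object.
#' @return Kinetic energy in MeV (vectorized).
#' @export
energy_from_range <- function(range_mm, const = beam_constants()) {
  stopifnot(is.numeric(range_mm), all(range_mm > 0))
  (range_mm / const$alpha)^(1 / const$p)
}

#' Momentum-velocity product of a proton
#'
#' `pv = T (T + 2 m) / (T + m)` in MeV, with `T` the kinetic energy and `m`
#' the proton rest energy. This is the quantity entering Highland's formula.
#'
#' @param energy Kinetic energy, MeV.
#' @param const A [beam_constants()] object.
#' @return `pv` in MeV (vectorized).
#' @export
proton_pv <- function(energy, const = beam_constants()) {
  m <- const$proton_mass
  energy * (energy + 2 * m) / (energy + m)
}

#' Water-equivalent thickness
#'
#' Scales a physical thickness by the material's water-equivalent thickness
#' ratio (WELR).
#'
#' @param physical_thickness Thickness in mm, >= 0.
#' @param wel_ratio Water-equivalent thickness ratio, > 0.
#' @return Water-equivalent thickness in mm.
#' @export
#' @examples
#' wel_scale(10, 0.97)
wel_scale <- function(physical_thickness, wel_ratio) {
  stopifnot(is.numeric(physical_thickness), is.numeric(wel_ratio))
  if (any(physical_thickness < 0)) stop("thickness must be >= 0", call. = FALSE)
  if (any(wel_ratio <= 0)) stop("wel_ratio must be > 0", call. = FALSE)
  physical_thickness * wel_ratio
}
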