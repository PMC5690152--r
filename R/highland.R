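# Highland parameterization of multiple Coulomb scattering.

#' Highland scattering angle for a slab
#'
#' RMS projected multiple-Coulomb-scattering angle of a proton traversing a
#' slab of water-equivalent path `path_length`:
#' `theta0 = (14.1 / pv) * sqrt(L / X0) * (1 + log10(L / X0) / 9)`,
#' with `pv` the momentum-velocity product evaluated from the proton's
#' current energy, recovered from its residual range by inverting the
#' Bragg-Kleeman law. The bracket is clamped at 0 for extremely thin slabs;
#' `L = 0` returns 0.
#'
#' The transport engine applies this formula in cumulative form: the kick
#' variance for a path increment is `theta0^2(l + dl) - theta0^2(l)` with
#' `l` the cumulative radiative path, so that consecutive slabs add in
#' variance exactly as a single combined slab (at fixed energy).
#'
#' @param residual_range Proton residual range in mm WEL (sets the energy).
#' @param path_length Slab water-equivalent path, mm, >= 0.
#' @param radiation_length Radiation length, mm; default water (360.8 mm).
#' @param const A [beam_constants()] object.
#' @return RMS projected angle in radian.
#' @export
#' @examples
#' highland_sigma(residual_range = range_from_energy(190), path_length = 10)
highland_sigma <- function(residual_range, path_length,
                           radiation_length = beam_constants()$x0_water,
                           const = beam_constants()) {
  stopifnot(path_length >= 0, radiation_length > 0, residual_range > 0)
  if (path_length == 0) return(0)
  pv <- proton_pv(energy_from_range(residual_range, const), const)
  t <- path_length / radiation_length
  bracket <- max(0, 1 + log10(t) / 9)
  (14.1 / pv) * sqrt(t) * bracket
}

# Dimensionless cumulative scattering-power integrand g(l) such that
# theta0^2 = (14.1 / pv)^2 * g(l): g(l) = (l/X0) * max(0, 1 + log10(l/X0)/9)^2.
# Monotone non-decreasing in l, so per-step variance increments are >= 0.
highland_g <- function(path_length, radiation_length) {
  t <- path_length / radiation_length
  out <- numeric(length(t))
  pos <- t > 0
  br <- pmax(0, 1 + log10(t[pos]) / 9)
  out[pos] <- t[pos] * br^2
  out
}
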