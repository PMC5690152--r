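# Reference (pure R) implementations of the per-proton transport steps.
# These mirror the C++ kernel operation for operation and are used for
# small-scale tests and inspection; run_simulation() uses the compiled
# kernel.

#' Transport protons through the beam-limiting device stack
#'
#' Sequentially applies the range shifter (residual-range loss plus Highland
#' kick), the range compensator (local water-equivalent thickness at the
#' crossing point), the aperture cut, and the vacuum drift to the phantom
#' entrance. Devices are thin: the range loss and scattering kick are
#' applied at the device plane. Scattering uses the cumulative-path Highland
#' form (see [highland_sigma()]).
#'
#' @param protons Data frame from [sample_source_protons()] (columns
#'   `x, y, z, dx, dy, dz, residual, alive, l_cum`).
#' @param config A [beamline_config()].
#' @param const A [beam_constants()] object.
#' @param scatter Apply scattering kicks in devices (uses R's RNG).
#' @param scatter_in_rs Apply the kick inside the range shifter.
#' @return The updated proton data frame; protons stopped in a device or
#'   cut by the aperture have `alive = FALSE`.
#' @export
transport_device_stack <- function(protons, config, const = beam_constants(),
                                   scatter = TRUE, scatter_in_rs = TRUE) {
  p <- protons
  ap_z <- -config$collimator_to_axis
  rs_z <- ap_z - 200
  kick <- function(p, wel, live) {
    l2 <- p$l_cum + wel
    if (scatter) {
      var <- (14.1 / proton_pv(energy_from_range(pmax(p$residual, 0.25), const), const))^2 *
        (highland_g(l2, const$x0_water) - highland_g(p$l_cum, const$x0_water))
      var <- pmax(var, 0)
      sg <- sqrt(var) * live
      p$dx <- p$dx + sg * rnorm(nrow(p))
      p$dy <- p$dy + sg * rnorm(nrow(p))
      nrm <- sqrt(p$dx^2 + p$dy^2 + p$dz^2)
      p$dx <- p$dx / nrm; p$dy <- p$dy / nrm; p$dz <- p$dz / nrm
    }
    p$l_cum <- ifelse(live, l2, p$l_cum)
    p
  }
  drift <- function(p, z1) {
    t <- (z1 - p$z) / p$dz
    p$x <- p$x + p$dx * t
    p$y <- p$y + p$dy * t
    p$z <- z1
    p
  }
  if (config$rs_thickness > 0) {
    p <- drift(p, rs_z)
    p$residual <- p$residual - ifelse(p$alive, config$rs_thickness, 0)
    stopped <- p$alive & p$residual <= 0
    p$alive[stopped] <- FALSE
    if (scatter_in_rs) p <- kick(p, config$rs_thickness, p$alive)
    else p$l_cum <- p$l_cum + ifelse(p$alive, config$rs_thickness, 0)
  }
  if (!is.null(config$compensator)) {
    p <- drift(p, -config$compensator$plane_distance)
    th <- compensator_thickness_at(config$compensator, p$x, p$y)
    p$residual <- p$residual - ifelse(p$alive, th, 0)
    stopped <- p$alive & p$residual <= 0
    p$alive[stopped] <- FALSE
    p <- kick(p, th * p$alive, p$alive & th > 0)
  }
  p <- drift(p, ap_z)
  inside <- point_in_aperture(config$aperture, p$x, p$y)
  p$alive <- p$alive & inside
  drift(p, -config$measurement_depth)
}

#' Deposit proton tracks in the phantom (reference implementation)
#'
#' Steps each living proton through the phantom in `step` increments along
#' its (scattered) direction; at each step deposits
#' `curve(R0 - residual + dw/2) * dw` (dw the water-equivalent step) into
#' the depth slice containing the step midpoint, sharing it bilinearly
#' (cloud-in-cell) over the four nearest voxel columns — each proton is
#' scored as a voxel-width pencil. One Highland kick per step. Deposition
#' continues (on a straight line, no further kicks) until the curve's
#' support ends: the measured-style curve carries the straggling tail
#' beyond the nominal range, and that dose belongs to the track. Small-n R
#' mirror of the compiled kernel.
#'
#' @param protons Data frame positioned at the phantom entrance (from
#'   [transport_device_stack()]).
#' @param curve The pristine [depth_dose_curve()] of the beam.
#' @param grid_origin (x, y, z) of the scoring-grid corner, mm.
#' @param dims Grid dimensions (nx, ny, nz).
#' @param welr Phantom water-equivalent ratio.
#' @param step Step length, mm.
#' @param vox Voxel size, mm.
#' @param const A [beam_constants()] object.
#' @param scatter Apply per-step Highland kicks (uses R's RNG).
#' @return 3-D dose array (raw deposit sums).
#' @export
deposit_in_phantom <- function(protons, curve, grid_origin, dims, welr = 1,
                               step = 2, vox = 2, const = beam_constants(),
                               scatter = TRUE) {
  R0 <- curve$nominal_range
  dose <- array(0, dims)
  curve_end <- max(curve$depths)
  zmax <- grid_origin[3] + dims[3] * vox
  for (i in which(protons$alive)) {
    x <- protons$x[i]; y <- protons$y[i]; z <- protons$z[i]
    ux <- protons$dx[i]; uy <- protons$dy[i]; uz <- protons$dz[i]
    r <- protons$residual[i]; l1 <- protons$l_cum[i]
    g1 <- highland_g(l1, const$x0_water)
    repeat {
      wcur <- R0 - r
      if (wcur >= curve_end) break
      ds <- step; dw <- step * welr
      dmid <- wcur + dw / 2
      val <- curve_value(curve, dmid)
      if (val > 0) {
        m <- c(x + ux * ds / 2, y + uy * ds / 2, z + uz * ds / 2)
        iz <- floor((m[3] - grid_origin[3]) / vox) + 1
        if (iz >= 1 && iz <= dims[3]) {
          # cloud-in-cell lateral splat (matches the compiled kernel)
          fx <- (m[1] - grid_origin[1]) / vox - 0.5
          fy <- (m[2] - grid_origin[2]) / vox - 0.5
          ix0 <- floor(fx); iy0 <- floor(fy)
          wx <- fx - ix0; wy <- fy - iy0
          for (cx in 0:1) for (cy in 0:1) {
            ix <- ix0 + cx + 1; iy <- iy0 + cy + 1
            if (ix < 1 || ix > dims[1] || iy < 1 || iy > dims[2]) next
            w <- (if (cx) wx else 1 - wx) * (if (cy) wy else 1 - wy)
            dose[ix, iy, iz] <- dose[ix, iy, iz] + val * dw * w
          }
        }
      }
      x <- x + ux * ds; y <- y + uy * ds; z <- z + uz * ds
      had_range <- r > 1e-9
      r <- r - dw
      if (had_range) {
        g2 <- highland_g(l1 + dw, const$x0_water)
        if (scatter && r > 0) {
          kf <- 14.1 / proton_pv(energy_from_range(max(r, 0.25), const), const)
          var <- kf^2 * (g2 - g1)
          if (var > 0) {
            sg <- sqrt(var)
            ux <- ux + sg * rnorm(1); uy <- uy + sg * rnorm(1)
            nrm <- sqrt(ux^2 + uy^2 + uz^2)
            ux <- ux / nrm; uy <- uy / nrm; uz <- uz / nrm
          }
        }
        l1 <- l1 + dw; g1 <- g2
      }
      if (z > zmax) break
    }
  }
  dose
}
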