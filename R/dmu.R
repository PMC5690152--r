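# DMU composition: detector-volume averaging, F_BSD lookup, paired-SMC
# F_PSD, the calculated field-size curve and the mean-radius field-size
# correction, and the final clinical DMU.

#' Detector cell
#'
#' Averaging volume representing the dosimeter: the Farmer-type reference
#' chamber is modelled by its rectangular lateral projection 6.1 mm x
#' 23.4 mm, the 2-D array unit chamber by 5 mm x 5 mm with its sensitive
#' center 8 mm WEL below the entrance surface.
#'
#' @param kind `"farmer"` or `"array_cell"`.
#' @return An object of class `detector_cell`.
#' @export
detector_cell <- function(kind = c("farmer", "array_cell")) {
  kind <- match.arg(kind)
  if (kind == "farmer") {
    structure(list(kind = kind, extent = c(6.1, 23.4), wel_offset = 0),
              class = "detector_cell")
  } else {
    structure(list(kind = kind, extent = c(5, 5), wel_offset = 8),
              class = "detector_cell")
  }
}

#' Detector-volume-averaged dose
#'
#' Mean dose over the detector cell's lateral rectangle centered at
#' `center`, at the cell's depth: the trilinearly interpolated dose is
#' averaged by midpoint quadrature on a fine sub-grid (exact for linear
#' dose gradients, partial-voxel overlaps included by construction).
#'
#' @param grid A `dose_grid`.
#' @param cell A [detector_cell()].
#' @param center (x, y, z) of the cell center, mm.
#' @param quad_spacing Quadrature sub-grid spacing, mm.
#' @return Dose per source proton averaged over the cell.
#' @export
detector_average <- function(grid, cell, center = c(0, 0, 0),
                             quad_spacing = 0.5) {
  stopifnot(inherits(grid, "dose_grid") || is.list(grid),
            inherits(cell, "detector_cell"))
  ex <- cell$extent
  lo <- center[1:2] - ex / 2
  hi <- center[1:2] + ex / 2
  gmin <- grid$origin[1:2]
  gmax <- grid$origin[1:2] + grid$dims[1:2] * grid$vox
  if (any(lo < gmin) || any(hi > gmax) ||
      center[3] < grid$origin[3] || center[3] > grid$origin[3] + grid$dims[3] * grid$vox) {
    stop("detector cell footprint outside the dose grid", call. = FALSE)
  }
  nqx <- max(1, ceiling(ex[1] / quad_spacing))
  nqy <- max(1, ceiling(ex[2] / quad_spacing))
  xs <- lo[1] + (seq_len(nqx) - 0.5) * ex[1] / nqx
  ys <- lo[2] + (seq_len(nqy) - 0.5) * ex[2] / nqy
  pts <- cbind(rep(xs, times = nqy), rep(ys, each = nqx), center[3])
  mean(dose_at(grid, pts))
}

# lightweight dose_grid view of one statistical batch (for per-batch
# detector averages)
batch_grid <- function(grid, b) {
  bi <- grid$batch_index
  structure(list(dose = grid$batch_dose[, , , b],
                 origin = c(grid$origin[1] + (bi[1] - 1) * grid$vox,
                            grid$origin[2] + (bi[1] - 1) * grid$vox,
                            grid$origin[3]),
                 vox = grid$vox,
                 dims = c(length(bi), length(bi), grid$dims[3]),
                 n_protons = grid$n_protons / grid$n_batches,
                 phantom_welr = grid$phantom_welr),
            class = "dose_grid")
}

#' Look up the beam-spreading-device factor
#'
#' Exact value at grid nodes; linear interpolation in range-shifter
#' thickness between nodes. Energy and SOBP width are categorical: no
#' interpolation across them. RS thickness outside the measured bounds is
#' an error (no extrapolation of a safety-critical quantity).
#'
#' @param table An [fbsd_table()].
#' @param energy Beam energy, MeV (must be tabulated).
#' @param sobp SOBP width, mm (must be tabulated).
#' @param rs Range-shifter thickness, mm WEL.
#' @return The factor F_BSD.
#' @export
#' @examples
#' lookup_fbsd(generate_fbsd_table(1), 190, 80, 0)   # 1
lookup_fbsd <- function(table, energy, sobp, rs) {
  stopifnot(inherits(table, "fbsd_table"))
  if (!energy %in% table$energy_mev) {
    stop("energy not in the F_BSD table (no interpolation across energy)", call. = FALSE)
  }
  g <- table[table$energy_mev == energy & table$sobp_mm == sobp, ]
  if (nrow(g) == 0) stop("SOBP width not in the F_BSD table for this energy", call. = FALSE)
  g <- g[order(g$rs_mm_wel), ]
  if (rs < min(g$rs_mm_wel) - 1e-9 || rs > max(g$rs_mm_wel) + 1e-9) {
    stop(sprintf("RS thickness %g mm outside the measured F_BSD bounds [%g, %g]",
                 rs, min(g$rs_mm_wel), max(g$rs_mm_wel)), call. = FALSE)
  }
  approx(g$rs_mm_wel, g$value, xout = rs)$y
}

#' Simulate the dose-per-MU proxy for one configuration
#'
#' Runs the SMC engine and returns the detector-averaged dose at the
#' measurement point, normalized per unit source fluence (dose per proton
#' times the fluence-window area). This is the calculation's DMU proxy:
#' ratios of it between configurations are the calculated factors. The
#' statistical error is estimated from per-batch detector averages.
#'
#' @param config A [beamline_config()].
#' @param commissioning A commissioning bundle.
#' @param tconfig A [transport_config()].
#' @param cell A [detector_cell()].
#' @param window_halfwidth Fluence-window half-width, mm. The default
#'   (40 mm) extends more than four lateral-scattering sigmas beyond the
#'   detector edge, so the excluded fluence cannot contribute to the scored
#'   dose.
#' @param keep_grid Keep the full `dose_grid` in the result.
#' @return A list of class `dmu_sim`: `value`, `se` (absolute), `rel_se`,
#'   `point`, `n_protons`, and optionally `grid`.
#' @export
simulate_dmu <- function(config, commissioning, tconfig,
                         cell = detector_cell("farmer"),
                         window_halfwidth = 40, keep_grid = FALSE) {
  point <- c(config$measurement_lateral, 0)
  grid <- run_simulation(config, tconfig, commissioning,
                         window_halfwidth = window_halfwidth,
                         window_center = config$measurement_lateral)
  v <- detector_average(grid, cell, point) * grid$fluence_area
  vb <- vapply(seq_len(grid$n_batches), function(b) {
    detector_average(batch_grid(grid, b), cell, point) * grid$fluence_area
  }, numeric(1))
  rel <- sd(vb) / (sqrt(grid$n_batches) * mean(vb))
  out <- list(value = v, se = abs(v) * rel, rel_se = rel, point = point,
              n_protons = grid$n_protons, seed = tconfig$seed)
  if (keep_grid) out$grid <- grid
  structure(out, class = "dmu_sim")
}

#' @export
print.dmu_sim <- function(x, ...) {
  cat(sprintf("<dmu_sim: %.5g +- %.2g (rel SE %.2f%%), %.3g protons>\n",
              x$value, x$se, 100 * x$rel_se, x$n_protons))
  invisible(x)
}

#' Patient-specific device factor F_PSD
#'
#' Ratio of the simulated DMU proxy in the fully patient-specific (PSD)
#' condition to that in the matching beam-spreading-only (BSD) condition.
#' Both configurations must share energy, SOBP width and RS thickness; the
#' two runs use different seeds so their errors are independent, and the
#' relative errors add in quadrature.
#'
#' @param bsd_config,psd_config [beamline_config()]s (BSD: standard
#'   collimator, no compensator, SOBP-center point; PSD: patient-specific).
#' @param commissioning A commissioning bundle.
#' @param tconfig A [transport_config()] (the PSD run uses `seed + 1`).
#' @param cell A [detector_cell()].
#' @param ... Passed to [simulate_dmu()].
#' @return List with `value`, `se` (absolute), `rel_se`, and the two
#'   underlying `dmu_sim` results.
#' @export
compute_fpsd <- function(bsd_config, psd_config, commissioning, tconfig,
                         cell = detector_cell("farmer"), ...) {
  same <- bsd_config$energy == psd_config$energy &&
    bsd_config$sobp_width == psd_config$sobp_width &&
    abs(bsd_config$rs_thickness - psd_config$rs_thickness) < 1e-9
  if (!same) {
    stop("BSD and PSD configurations must share energy, SOBP width and RS thickness",
         call. = FALSE)
  }
  num_t <- tconfig
  num_t$seed <- tconfig$seed + 1L
  den <- simulate_dmu(bsd_config, commissioning, tconfig, cell, ...)
  num <- simulate_dmu(psd_config, commissioning, num_t, cell, ...)
  if (den$value <= 0) stop("zero BSD denominator in F_PSD", call. = FALSE)
  f <- num$value / den$value
  rel <- sqrt(num$rel_se^2 + den$rel_se^2)
  list(value = f, se = abs(f) * rel, rel_se = rel, psd = num, bsd = den)
}

#' Calculated field-size curve
#'
#' Simulated DMU proxy at the center of the SOBP for square apertures of
#' the given sides in the FS condition (0 mm RS, 80 mm SOBP), normalized to
#' the 185 mm square.
#'
#' @param energy Beam energy, MeV.
#' @param commissioning A commissioning bundle.
#' @param tconfig A [transport_config()] (run `i` uses `seed + i`).
#' @param sides Square aperture sides, mm (must include 185).
#' @param cell A [detector_cell()].
#' @param ... Passed to [simulate_dmu()].
#' @return A [field_size_table()] with `kind = "calculated"`; attribute
#'   `rel_se` holds the per-side relative errors.
#' @export
compute_fcalc_fs <- function(energy, commissioning, tconfig,
                             sides = FS_APERTURE_SIDES,
                             cell = detector_cell("farmer"), ...) {
  if (!185 %in% sides) stop("sides must include the 185 mm normalization square",
                            call. = FALSE)
  vals <- numeric(length(sides))
  rels <- numeric(length(sides))
  for (i in seq_along(sides)) {
    tc <- tconfig
    tc$seed <- tconfig$seed + i
    sim <- simulate_dmu(fs_config(energy, sides[i]), commissioning, tc, cell, ...)
    vals[i] <- sim$value
    rels[i] <- sim$rel_se
  }
  ref <- vals[sides == 185]
  f <- vals / ref
  f[sides == 185] <- 1
  tab <- field_size_table(energy, sides, pmin(f, 1.01), kind = "calculated")
  attr(tab, "rel_se") <- rels[order(sides)]
  tab
}

#' Field-size correction factor F_FS(A)
#'
#' Ratio of the measured to the calculated field-size curve, evaluated at
#' the clinical aperture's mean radius: each table's square side A is
#' mapped to the mean center-to-perimeter radius of that square, both
#' curves are interpolated linearly in mean-radius space, and their ratio
#' is returned. Mean radii beyond the largest tabulated square clamp to 1
#' (no correction); radii below the smallest tabulated square are an error
#' (outside the validated domain).
#'
#' @param fmeas_table Measured [field_size_table()].
#' @param fcalc_table Calculated [field_size_table()] (same energy).
#' @param aperture The clinical [aperture_collimator()].
#' @return The correction factor.
#' @export
field_size_correction <- function(fmeas_table, fcalc_table, aperture) {
  stopifnot(inherits(fmeas_table, "field_size_table"),
            inherits(fcalc_table, "field_size_table"))
  if (fmeas_table$energy != fcalc_table$energy) {
    stop("measured and calculated tables are for different energies", call. = FALSE)
  }
  rho <- mean_aperture_radius(aperture)
  rm <- square_mean_radius(fmeas_table$aperture_sides)
  rc <- square_mean_radius(fcalc_table$aperture_sides)
  if (rho > max(rm) || rho > max(rc)) return(1.0)
  if (rho < min(rm) || rho < min(rc)) {
    stop(sprintf("mean aperture radius %.1f mm below the smallest tabulated square (validated domain)",
                 rho), call. = FALSE)
  }
  fm <- approx(rm, fmeas_table$f_values, xout = rho)$y
  fc <- approx(rc, fcalc_table$f_values, xout = rho)$y
  fm / fc
}

#' Compose the clinical DMU
#'
#' `DMU_clinical = DMU_STD x F_BSD x F_PSD x F_FS`. Only F_PSD carries
#' Monte Carlo error; F_BSD and the measured field-size curve are treated
#' as exact measured inputs.
#'
#' @param dmu_std Measured standard DMU (opaque scalar).
#' @param f_bsd,f_psd,f_fs The three factors, all > 0.
#' @param statistical_error Relative (fractional) statistical error of
#'   `f_psd`, propagated to the result.
#' @return An object of class `dmu_result`.
#' @export
#' @examples
#' compose_clinical_dmu(1.0, 0.9, 1.02, 0.98)
compose_clinical_dmu <- function(dmu_std, f_bsd, f_psd, f_fs,
                                 statistical_error = 0) {
  if (any(c(dmu_std, f_bsd, f_psd, f_fs) <= 0)) {
    stop("DMU_STD and all factors must be positive", call. = FALSE)
  }
  f_clin <- f_bsd * f_psd * f_fs
  structure(list(dmu_std = dmu_std, dmu_clinical = dmu_std * f_clin,
                 breakdown = list(f_bsd = f_bsd, f_psd = f_psd, f_fs = f_fs,
                                  f_clinical = f_clin,
                                  statistical_error = statistical_error)),
            class = "dmu_result")
}

#' @export
print.dmu_result <- function(x, ...) {
  b <- x$breakdown
  cat(sprintf("Clinical DMU: %.5g  (DMU_STD %.5g x F_clinical %.5g)\n",
              x$dmu_clinical, x$dmu_std, b$f_clinical))
  cat(sprintf("  F_BSD %.4f x F_PSD %.4f x F_FS %.4f   (rel SE %.2f%%)\n",
              b$f_bsd, b$f_psd, b$f_fs, 100 * b$statistical_error))
  invisible(x)
}

#' Full clinical DMU calculation for one field
#'
#' Orchestrates the three factors for a patient-specific (PSD)
#' configuration: F_BSD from the commissioning table, F_PSD from a paired
#' SMC run against the matching BSD condition, and F_FS from the measured
#' and calculated field-size curves at the field's mean aperture radius.
#'
#' @param psd_config Patient-specific [beamline_config()].
#' @param commissioning A commissioning bundle.
#' @param dmu_std Measured standard DMU.
#' @param tconfig A [transport_config()].
#' @param cell A [detector_cell()].
#' @param fcalc_table Optional precomputed calculated [field_size_table()]
#'   for this energy (otherwise computed with [compute_fcalc_fs()], five
#'   additional simulations).
#' @param ... Passed to [simulate_dmu()].
#' @return A `dmu_result` with attribute `"fpsd"` (the paired-run detail).
#' @export
clinical_dmu <- function(psd_config, commissioning, dmu_std = 1,
                         tconfig = transport_config(),
                         cell = detector_cell("farmer"),
                         fcalc_table = NULL, ...) {
  e <- psd_config$energy
  f_bsd <- lookup_fbsd(commissioning$fbsd, e, psd_config$sobp_width,
                       psd_config$rs_thickness)
  bsd <- bsd_config(e, psd_config$sobp_width, psd_config$rs_thickness,
                    phantom_welr = psd_config$phantom_welr,
                    const = commissioning$const)
  fpsd <- compute_fpsd(bsd, psd_config, commissioning, tconfig, cell, ...)
  if (is.null(fcalc_table)) {
    fc_t <- tconfig
    fc_t$seed <- tconfig$seed + 100L
    fcalc_table <- compute_fcalc_fs(e, commissioning, fc_t, cell = cell, ...)
  }
  f_fs <- field_size_correction(commissioning$fmeas_fs[[as.character(e)]],
                                fcalc_table, psd_config$aperture)
  out <- compose_clinical_dmu(dmu_std, f_bsd, fpsd$value, f_fs,
                              statistical_error = fpsd$rel_se)
  attr(out, "fpsd") <- fpsd
  out
}
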