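# Simplified Monte Carlo engine: source sampling, the batched run driver
# around the C++ transport kernel, and the dose-grid container with batch
# statistics.

#' Transport configuration
#'
#' Particle budget and stepping parameters of a simulation. Protons are
#' split into `n_batches` equal, independently seeded batches; the
#' batch-to-batch spread of any scored quantity gives its statistical error.
#' The default particle count is set so that the relative statistical error
#' of the dose in the 2 mm voxel at the measurement point is below 1% for
#' the commissioning geometries.
#'
#' @param n_protons Total number of source protons (rounded up to a multiple
#'   of `n_batches`).
#' @param n_batches Number of statistical batches (>= 2).
#' @param seed Integer seed; a fixed seed makes the whole run bit-identical.
#' @param step Phantom step length, mm; must not exceed the 2 mm voxel.
#' @param scatter Master switch for Highland scattering (disable only for
#'   geometric tests).
#' @param scatter_in_rs Apply the scattering kick inside the range shifter
#'   (on by default; the alternative folds shifter scatter into the
#'   effective source).
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(n_protons = 2.4e7, n_batches = 20, seed = 1L,
                             step = 2, scatter = TRUE, scatter_in_rs = TRUE) {
  stopifnot(n_protons >= n_batches, n_batches >= 2, step > 0, step <= 2)
  per <- ceiling(n_protons / n_batches)
  structure(list(n_protons = per * n_batches, n_batches = as.integer(n_batches),
                 per_batch = per, seed = as.integer(seed), step = step,
                 scatter = isTRUE(scatter), scatter_in_rs = isTRUE(scatter_in_rs)),
            class = "transport_config")
}

# deterministic sub-seed for batch b (kept well below 2^31)
batch_seed <- function(seed, b) {
  (abs(seed) %% 1000003L) * 1009L + b * 9973L
}

#' Sample protons from the effective source
#'
#' Draws one batch of proton initial states: aim points uniform over a
#' square fluence window in the isocenter plane, source positions Gaussian
#' (`lateral_sigma`) in the source plane, directions along the
#' source-to-aim ray plus Gaussian angular noise (`angular_sigma`), and the
#' initial residual range assigned by sampling one SOBP constituent with
#' probability proportional to its weight. With
#' `source_to_axis_distance = Inf` the beam is parallel. Uses R's RNG
#' stream: seed the generator before calling for reproducibility.
#'
#' @param source An [effective_source()].
#' @param n Number of protons.
#' @param sobp An [sobp_spec()] (or the `$spec` of [build_sobp()]).
#' @param nominal_range Pristine range of the beam, mm WEL (residual range
#'   of constituent `j` is `nominal_range - shifts[j]`).
#' @param rs_thickness Pre-degradation applied later by the device stack
#'   (not used here; the full residual is assigned).
#' @param window_halfwidth Half-width of the square fluence window, mm.
#' @param window_center Lateral (x, y) center of the window, mm.
#' @return A data frame with columns `x, y, z, dx, dy, dz, residual,
#'   constituent, alive, l_cum` — positions at the source plane (or the
#'   isocenter plane for a parallel beam), unit directions, residual range
#'   in mm WEL.
#' @export
sample_source_protons <- function(source, n, sobp, nominal_range,
                                  window_halfwidth, window_center = c(0, 0),
                                  rs_thickness = 0) {
  stopifnot(inherits(source, "effective_source"), n >= 1, window_halfwidth > 0)
  if (inherits(sobp, "sobp")) sobp <- sobp$spec
  stopifnot(inherits(sobp, "sobp_spec"))
  aimx <- runif(n, window_center[1] - window_halfwidth,
                window_center[1] + window_halfwidth)
  aimy <- runif(n, window_center[2] - window_halfwidth,
                window_center[2] + window_halfwidth)
  if (is.finite(source$sad)) {
    sx <- if (source$lateral_sigma > 0) rnorm(n, 0, source$lateral_sigma) else numeric(n)
    sy <- if (source$lateral_sigma > 0) rnorm(n, 0, source$lateral_sigma) else numeric(n)
    ux <- (aimx - sx) / source$sad
    uy <- (aimy - sy) / source$sad
    px <- sx; py <- sy; pz <- -source$sad
  } else {
    ux <- numeric(n); uy <- numeric(n)
    px <- aimx; py <- aimy; pz <- 0
  }
  if (source$angular_sigma > 0) {
    ux <- ux + rnorm(n, 0, source$angular_sigma)
    uy <- uy + rnorm(n, 0, source$angular_sigma)
  }
  dz <- 1 / sqrt(1 + ux^2 + uy^2)
  k <- sample.int(length(sobp$weights), n, replace = TRUE, prob = sobp$weights)
  data.frame(x = px, y = py, z = pz, dx = ux * dz, dy = uy * dz, dz = dz,
             residual = nominal_range - sobp$shifts[k], constituent = k,
             alive = TRUE, l_cum = 0)
}

# Highland lookup tables shared by the C++ kernel and the R reference
# transport: kfac(r) = 14.1/pv at residual range r, and the cumulative
# scattering-power g(l).
highland_tables <- function(const, r_max = 400, dr = 0.5,
                            l_max = 800, dl = 0.5) {
  r <- seq(0, r_max, by = dr)
  en <- energy_from_range(pmax(r, 0.25), const)
  list(kfac = 14.1 / proton_pv(en, const), dr = dr,
       g = highland_g(seq(0, l_max, by = dl), const$x0_water), dl = dl)
}

# automatic fluence-window half-width: cover the aperture opening projected
# into the isocenter plane, plus margin for source blur and divergence
auto_window <- function(config, source, margin = 25) {
  ext <- max(abs(config$aperture$edge_points))
  if (is.finite(source$sad)) {
    ext <- ext * source$sad / (source$sad - config$collimator_to_axis)
  }
  ext + margin
}

#' Run a simplified Monte Carlo simulation
#'
#' Full pipeline for one beamline configuration: build the SOBP, sample
#' protons from the effective source over a square fluence window, degrade
#' and scatter them through the range shifter, compensator and aperture,
#' and deposit the pristine depth-dose curve along each track in the
#' voxelized phantom (2 mm voxels, one Highland kick per step). Each of the
#' `n_batches` batches uses an independent sub-seed; a fixed seed gives a
#' bit-identical `dose_grid`.
#'
#' `window_halfwidth` restricts the sampled fluence to a square around
#' `window_center` (default: the full projected aperture). All doses are
#' relative and normalized per source proton; the `fluence_area` field
#' (window area) converts them to per-unit-fluence for comparisons across
#' different windows.
#'
#' @param config A [beamline_config()].
#' @param tconfig A [transport_config()].
#' @param commissioning A [synthesize_commissioning()] bundle.
#' @param window_halfwidth Fluence window half-width, mm (default: cover
#'   the aperture).
#' @param window_center Lateral center of the fluence window, mm.
#' @param grid_halfwidth Lateral half-extent of the scoring grid, mm
#'   (default `window_halfwidth + 20`).
#' @param batch_halfwidth Lateral half-extent of the region whose per-batch
#'   doses are kept for statistical errors, mm.
#' @return A `dose_grid` object.
#' @export
run_simulation <- function(config, tconfig, commissioning,
                           window_halfwidth = NULL, window_center = NULL,
                           grid_halfwidth = NULL, batch_halfwidth = 32) {
  stopifnot(inherits(config, "beamline_config"),
            inherits(tconfig, "transport_config"),
            inherits(commissioning, "commissioning"))
  source <- commissioning$source
  const <- commissioning$const
  sobp <- commissioning_sobp(commissioning, config$energy, config$sobp_width)
  R0 <- sobp$pristine$nominal_range
  if (is.null(window_center)) window_center <- config$measurement_lateral
  if (is.null(window_halfwidth)) {
    window_halfwidth <- auto_window(config, source)
    window_center <- c(0, 0)
  }
  if (is.null(grid_halfwidth)) grid_halfwidth <- window_halfwidth + 20
  vox <- 2
  nhalf <- ceiling(grid_halfwidth / vox)
  nx <- 2L * nhalf + 1L                    # odd: central voxel brackets the axis
  gx0 <- -nx * vox / 2
  ent_z <- -config$measurement_depth
  track_phys <- (R0 - config$rs_thickness) / config$phantom_welr
  nz <- as.integer(ceiling((track_phys + 10) / vox))
  if (-ent_z >= nz * vox) stop("measurement depth beyond the scoring grid", call. = FALSE)

  ht <- highland_tables(const)
  ap <- config$aperture
  comp <- config$compensator
  has_comp <- !is.null(comp)
  comp_th <- if (has_comp) comp$thickness else matrix(0, 2, 2)
  ap_z <- -config$collimator_to_axis
  comp_z <- if (has_comp) -comp$plane_distance else ap_z - 30
  rs_z <- ap_z - 200

  # per-batch doses kept on a lateral sub-box (all depths)
  bh <- ceiling(batch_halfwidth / vox)
  cx <- nhalf + 1L                          # index of the axis voxel
  bi <- max(1L, cx - bh):min(nx, cx + bh)
  batch_dose <- array(0, c(length(bi), length(bi), nz, tconfig$n_batches))
  total <- array(0, c(nx, nx, nz))
  n_killed <- 0L; n_entered <- 0L

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (b in seq_len(tconfig$n_batches)) {
    sseed <- batch_seed(tconfig$seed, b)
    set.seed(sseed)
    p <- sample_source_protons(source, tconfig$per_batch, sobp, R0,
                               window_halfwidth, window_center)
    res <- smc_batch_cpp(p$x, p$y, p$z[1], p$dx, p$dy, p$dz, p$residual,
                         config$rs_thickness, rs_z,
                         has_comp, comp_th,
                         if (has_comp) comp$origin[1] else 0,
                         if (has_comp) comp$origin[2] else 0,
                         if (has_comp) comp$spacing else 1,
                         if (has_comp) comp$wel_ratio else 1,
                         comp_z,
                         TRUE, ap$edge_points[, 1], ap$edge_points[, 2], ap_z,
                         ent_z, config$phantom_welr, tconfig$step,
                         gx0, gx0, nx, nx, nz, vox,
                         sobp$pristine$values, sobp$pristine$spacing, R0,
                         ht$kfac, ht$dr, ht$g, ht$dl,
                         tconfig$scatter, tconfig$scatter_in_rs, tconfig$scatter,
                         sseed)
    dim(res$dose) <- c(nz, nx, nx)
    res$dose <- aperm(res$dose, c(2, 3, 1))
    total <- total + res$dose
    batch_dose[, , , b] <- res$dose[bi, bi, , drop = FALSE]
    n_killed <- n_killed + res$n_killed
    n_entered <- n_entered + res$n_entered
  }
  if (n_entered == 0L) {
    stop("no protons survived the device stack (aperture/energy misconfiguration)",
         call. = FALSE)
  }
  structure(list(dose = total, batch_dose = batch_dose, batch_index = bi,
                 origin = c(gx0, gx0, ent_z), vox = vox,
                 dims = c(nx, nx, nz),
                 n_protons = tconfig$n_protons, n_batches = tconfig$n_batches,
                 seed = tconfig$seed,
                 window_halfwidth = window_halfwidth,
                 window_center = window_center,
                 fluence_area = (2 * window_halfwidth)^2,
                 phantom_welr = config$phantom_welr,
                 n_killed = n_killed, n_entered = n_entered,
                 energy = config$energy, sobp_width = config$sobp_width,
                 rs_thickness = config$rs_thickness,
                 condition = config$condition_label),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid %s: %dx%dx%d voxels @ %g mm, %.3g protons (%.0f%% through aperture), seed %d>\n",
              x$condition, x$dims[1], x$dims[2], x$dims[3], x$vox,
              x$n_protons, 100 * x$n_entered / x$n_protons, x$seed))
  invisible(x)
}

# voxel index (1-based triplet) containing a point, or NULL if outside
voxel_index <- function(grid, point) {
  i <- floor((point - grid$origin) / grid$vox) + 1
  if (any(i < 1) || any(i > grid$dims)) return(NULL)
  as.integer(i)
}

#' Trilinear dose interpolation
#'
#' Per-proton dose at arbitrary points, trilinear between voxel centers
#' (clamped at the grid boundary).
#'
#' @param grid A `dose_grid`.
#' @param points Numeric matrix with columns x, y, z (mm) or a length-3
#'   vector.
#' @return Dose per source proton at each point.
#' @export
dose_at <- function(grid, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  u <- sweep(points, 2, grid$origin) / grid$vox - 0.5   # voxel-center units
  d <- grid$dims
  val <- numeric(nrow(points))
  i0 <- pmin(pmax(floor(u), 0), matrix(rep(d - 2, each = nrow(u)), ncol = 3))
  f <- pmin(pmax(u - i0, 0), 1)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[, 1] else 1 - f[, 1]) *
         (if (cy) f[, 2] else 1 - f[, 2]) *
         (if (cz) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + cx + 1, i0[, 2] + cy + 1, i0[, 3] + cz + 1)
    val <- val + w * grid$dose[idx]
  }
  val / grid$n_protons
}

#' Batch-based statistical error of a voxel dose
#'
#' Relative standard error of the mean over the per-batch sub-totals of the
#' voxel containing `point`: `sd(batches) / (sqrt(n_batches) * mean)`.
#'
#' @param grid A `dose_grid` from [run_simulation()].
#' @param point (x, y, z) in mm; must lie in the batch-tracked region.
#' @return Relative standard error (fraction).
#' @export
estimate_statistical_error <- function(grid, point = c(0, 0, 0)) {
  stopifnot(inherits(grid, "dose_grid"))
  i <- voxel_index(grid, point)
  if (is.null(i)) stop("point outside the scoring grid", call. = FALSE)
  bi <- match(i[1], grid$batch_index)
  bj <- match(i[2], grid$batch_index)
  if (is.na(bi) || is.na(bj)) {
    stop("point outside the batch-tracked region", call. = FALSE)
  }
  v <- grid$batch_dose[bi, bj, i[3], ]
  m <- mean(v)
  if (m <= 0) stop("zero mean dose in the queried voxel; statistical error undefined",
                   call. = FALSE)
  sd(v) / (sqrt(grid$n_batches) * m)
}

#' Laterally integrated depth dose
#'
#' Sum of the deposited dose over each depth slice, per proton, against
#' water-equivalent depth (slice centers). For a broad beam this must
#' reproduce the input SOBP curve.
#'
#' @param grid A `dose_grid`.
#' @return Data frame with `depth_wel` (mm) and `dose` columns.
#' @export
integrated_depth_dose <- function(grid) {
  v <- apply(grid$dose, 3, sum) / grid$n_protons
  z <- (seq_len(grid$dims[3]) - 0.5) * grid$vox * grid$phantom_welr
  data.frame(depth_wel = z, dose = v)
}

#' Dose grid file I/O
#'
#' `write_dose_grid()` stores the raw voxel sums as a flat little-endian
#' double array with a JSON sidecar (`<path>.json`: dims, voxel spacing,
#' origin, particle count, seed, fluence window) so a run is reproducible
#' from its header. `read_dose_grid()` reconstructs the grid (without the
#' per-batch sub-totals, which stay in memory only).
#' `write_plane_csv()` exports one depth slice as CSV (`x_mm, y_mm, dose`)
#' for profile comparison.
#'
#' @param grid A `dose_grid`.
#' @param path Output path (the JSON header gets `.json` appended).
#' @param z Depth plane (grid z coordinate, mm).
#' @return Readers return the object; writers return `path` invisibly.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  con <- file(path, "wb")
  writeBin(as.vector(grid$dose), con, size = 8, endian = "little")
  close(con)
  hdr <- list(dims = grid$dims, voxel_mm = grid$vox, origin_mm = grid$origin,
              n_protons = grid$n_protons, n_batches = grid$n_batches,
              seed = grid$seed, window_halfwidth_mm = grid$window_halfwidth,
              window_center_mm = grid$window_center,
              fluence_area_mm2 = grid$fluence_area,
              phantom_welr = grid$phantom_welr, condition = grid$condition,
              energy_mev = grid$energy, sobp_mm = grid$sobp_width,
              rs_mm_wel = grid$rs_thickness,
              n_killed = grid$n_killed, n_entered = grid$n_entered)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(hdr$dims)
  con <- file(path, "rb")
  d <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  structure(list(dose = array(d, as.numeric(hdr$dims)), batch_dose = NULL,
                 batch_index = integer(0), origin = as.numeric(hdr$origin_mm),
                 vox = hdr$voxel_mm, dims = as.numeric(hdr$dims),
                 n_protons = as.numeric(hdr$n_protons),
                 n_batches = hdr$n_batches,
                 seed = hdr$seed,
                 window_halfwidth = hdr$window_halfwidth_mm,
                 window_center = as.numeric(hdr$window_center_mm),
                 fluence_area = hdr$fluence_area_mm2,
                 phantom_welr = hdr$phantom_welr,
                 n_killed = hdr$n_killed, n_entered = hdr$n_entered,
                 energy = hdr$energy_mev, sobp_width = hdr$sobp_mm,
                 rs_thickness = hdr$rs_mm_wel, condition = hdr$condition),
            class = "dose_grid")
}

#' @rdname write_dose_grid
#' @export
write_plane_csv <- function(grid, z, path) {
  stopifnot(inherits(grid, "dose_grid"))
  iz <- floor((z - grid$origin[3]) / grid$vox) + 1
  if (iz < 1 || iz > grid$dims[3]) stop("plane outside the grid", call. = FALSE)
  x <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * grid$vox
  y <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * grid$vox
  df <- data.frame(x_mm = rep(x, times = grid$dims[2]),
                   y_mm = rep(y, each = grid$dims[1]),
                   dose = as.vector(grid$dose[, , iz]) / grid$n_protons)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("x_mm,y_mm,dose", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", df$x_mm, df$y_mm, df$dose), con)
  invisible(path)
}
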