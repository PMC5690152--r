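# Field-set comparison statistics, positional-uncertainty bars and plane
# profile comparison.

#' Field-set difference statistics
#'
#' Summary of `f_calc - f_meas` over a set of clinical fields, in
#' percentage points: mean, sample standard deviation (n - 1 denominator),
#' the largest overestimation (max) and underestimation (min), and
#' optionally the fraction of fields within a closed band `|diff| <= band`.
#'
#' @param f_calc,f_meas Calculated and measured clinical factors (same
#'   length, > 0), or alternatively `f_calc` may be a data frame of field
#'   records with columns `f_calc_clinical` and `f_meas_clinical`.
#' @param band_percent Optional band half-width in percentage points.
#' @return An object of class `diff_summary` with fields `mean`, `sd`,
#'   `max`, `min`, `n_fields`, and `fraction_within` (if a band was given).
#' @export
#' @examples
#' diff_statistics(c(1.01, 0.99), c(1.00, 1.00))
diff_statistics <- function(f_calc, f_meas = NULL, band_percent = NULL) {
  if (is.data.frame(f_calc)) {
    f_meas <- f_calc$f_meas_clinical
    f_calc <- f_calc$f_calc_clinical
  }
  if (length(f_calc) < 2) stop("need at least 2 fields", call. = FALSE)
  stopifnot(length(f_calc) == length(f_meas))
  if (any(f_calc <= 0) || any(f_meas <= 0)) {
    stop("clinical factors must be positive", call. = FALSE)
  }
  d <- 100 * (f_calc - f_meas)
  out <- list(mean = mean(d), sd = sd(d), max = max(d), min = min(d),
              n_fields = length(d), diffs = d)
  if (!is.null(band_percent)) {
    out$band <- band_percent
    out$fraction_within <- mean(abs(d) <= band_percent)
  }
  structure(out, class = "diff_summary")
}

#' @export
print.diff_summary <- function(x, ...) {
  cat(sprintf("Difference over %d fields [percentage points]:\n", x$n_fields))
  cat(sprintf("  mean %+0.2f  sd %0.2f  max %+0.2f  min %+0.2f\n",
              x$mean, x$sd, x$max, x$min))
  if (!is.null(x$fraction_within)) {
    cat(sprintf("  within +-%.1f%%: %.0f%% of fields\n",
                x$band, 100 * x$fraction_within))
  }
  invisible(x)
}

#' Positional dose uncertainty around a point
#'
#' Peak-to-peak dose variation `(max - min)/mean` over a cube (default
#' 2 mm on a side) centered at the point, with the dose trilinearly
#' resampled on a sub-voxel lattice over the cube. Used as the error bar
#' for F_PSD and F_calc against setup error.
#'
#' @param grid A `dose_grid`.
#' @param point Cube center (x, y, z), mm.
#' @param cube_side Cube side, mm.
#' @param n_samples Lattice points per axis (corners included).
#' @return Peak-to-peak variation as a fraction of the mean.
#' @export
positional_uncertainty <- function(grid, point = c(0, 0, 0), cube_side = 2,
                                   n_samples = 5) {
  stopifnot(cube_side > 0, n_samples >= 2)
  s <- seq(-cube_side / 2, cube_side / 2, length.out = n_samples)
  pts <- as.matrix(expand.grid(x = point[1] + s, y = point[2] + s,
                               z = point[3] + s))
  lo <- grid$origin
  hi <- grid$origin + grid$dims * grid$vox
  if (any(apply(pts, 2, min) < lo) || any(apply(pts, 2, max) > hi)) {
    stop("cube extends outside the dose grid", call. = FALSE)
  }
  v <- dose_at(grid, pts)
  m <- mean(v)
  if (m <= 0) stop("zero mean dose in the cube", call. = FALSE)
  (max(v) - min(v)) / m
}

#' Compare two dose planes
#'
#' Pointwise differences between a calculated and a measured plane sampled
#' on the same lattice (e.g. the 27 x 27, 10 mm pitch 2-D array), both
#' already normalized by the standard-condition reference. Returns the
#' difference matrix and its summary.
#'
#' @param calc_plane,meas_plane Numeric matrices on the same lattice.
#' @return List with `diff` (matrix, calc - meas), `mean`, `sd`, `max`,
#'   `min`.
#' @export
compare_profiles <- function(calc_plane, meas_plane) {
  calc_plane <- as.matrix(calc_plane)
  meas_plane <- as.matrix(meas_plane)
  if (!all(dim(calc_plane) == dim(meas_plane))) {
    stop("planes must share the same lattice", call. = FALSE)
  }
  d <- calc_plane - meas_plane
  list(diff = d, mean = mean(d), sd = sd(as.vector(d)),
       max = max(d), min = min(d))
}

#' Sample a dose grid on the 2-D array lattice
#'
#' Detector-cell averages on the 27 x 27, 10 mm pitch lattice of 5 mm x
#' 5 mm array chambers, at depth `z` (defaults to the array's sensitive
#' plane: 8 mm WEL below the entrance).
#'
#' @param grid A `dose_grid`.
#' @param z Depth plane, mm (grid z coordinate).
#' @param n Lattice size per axis.
#' @param pitch Lattice pitch, mm.
#' @return `n x n` matrix of cell-averaged doses (NA where the cell falls
#'   outside the grid).
#' @export
seven29_plane <- function(grid, z = NULL, n = 27, pitch = 10) {
  cell <- detector_cell("array_cell")
  if (is.null(z)) z <- grid$origin[3] + cell$wel_offset / grid$phantom_welr
  off <- (seq_len(n) - (n + 1) / 2) * pitch
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- tryCatch(detector_average(grid, cell, c(off[i], off[j], z)),
                  error = function(e) NA_real_)
    out[i, j] <- v
  }
  out
}

#' Field record set I/O
#'
#' A field set is a CSV with columns `field_id, site, energy_mev, sobp_mm,
#' rs_mm_wel, f_meas_clinical` and optionally `f_calc_clinical` and device
#' file references; all factors must be positive.
#'
#' @param path CSV path.
#' @param records Data frame of field records.
#' @return `read_field_set` returns the validated data frame.
#' @export
read_field_set <- function(path) {
  df <- read.csv(path)
  need <- c("field_id", "site", "energy_mev", "sobp_mm", "rs_mm_wel",
            "f_meas_clinical")
  if (!all(need %in% names(df))) {
    stop("field set needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(df$f_meas_clinical <= 0)) {
    stop("f_meas_clinical must be positive", call. = FALSE)
  }
  df
}

#' @rdname read_field_set
#' @export
write_field_set <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
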