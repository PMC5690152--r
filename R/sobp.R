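# Spread-out Bragg peak synthesis: nonnegative least-squares ridge-filter
# weights against a flat target over the modulated region.

#' SOBP specification
#'
#' Weights and range shifts of the constituent pristine peaks that form a
#' spread-out Bragg peak. Constituent `j` is the pristine curve pulled back
#' by `shifts[j]` mm WEL; the transport engine realizes the SOBP by sampling
#' constituents with probability proportional to `weights`.
#'
#' @param energy Beam energy, MeV (one of 150, 190, 235).
#' @param width SOBP width in mm WEL, on the 30..100 by 10 grid.
#' @param shifts Range pull-backs of the constituent peaks, mm WEL, >= 0.
#' @param weights Nonnegative constituent weights; at least one > 0.
#' @return An object of class `sobp_spec`.
#' @export
sobp_spec <- function(energy, width, shifts, weights) {
  if (!energy %in% BEAM_ENERGIES) {
    stop("energy must be one of ", paste(BEAM_ENERGIES, collapse = ", "), call. = FALSE)
  }
  if (!width %in% SOBP_WIDTHS) {
    stop("SOBP width must be on the 30..100 mm by 10 mm grid", call. = FALSE)
  }
  stopifnot(length(shifts) == length(weights), all(shifts >= 0))
  if (any(weights < 0) || !any(weights > 0)) {
    stop("weights must be >= 0 with at least one > 0", call. = FALSE)
  }
  structure(list(energy = energy, width = width,
                 shifts = as.numeric(shifts), weights = as.numeric(weights)),
            class = "sobp_spec")
}

#' @export
print.sobp_spec <- function(x, ...) {
  cat(sprintf("<sobp_spec: %g MeV, width %g mm, %d constituents>\n",
              x$energy, x$width, length(x$shifts)))
  invisible(x)
}

#' Build a spread-out Bragg peak
#'
#' Solves nonnegative least-squares weights for range-shifted copies of the
#' analytic pristine curve so that their sum is flat over the modulated
#' region `[R - width, R]` (R the pristine range). The returned curve is
#' normalized to 1.0 at the SOBP center depth `R - width/2`.
#'
#' @param energy Beam energy, MeV.
#' @param width SOBP width, mm WEL, on the 30..100 by 10 grid.
#' @param grid_spacing Depth grid spacing, mm.
#' @param shift_step Spacing of constituent range pull-backs, mm.
#' @param flatness_tol Maximum allowed `(max - min)/mean` over the modulated
#'   region (evaluated with 2 mm margins); exceeding it is an error.
#' @param const A [beam_constants()] object.
#' @param pristine Optionally a precomputed pristine [depth_dose_curve()]
#'   for this energy (must share `grid_spacing`).
#' @return A list of class `sobp` with elements `spec` ([sobp_spec()]),
#'   `curve` ([depth_dose_curve()] with label `"sobp"`), and the achieved
#'   `flatness`.
#' @export
#' @examples
#' s <- build_sobp(190, 80)
#' s$flatness
build_sobp <- function(energy, width, grid_spacing = 0.5, shift_step = 2.5,
                       flatness_tol = 0.02, const = beam_constants(),
                       pristine = NULL) {
  if (!width %in% SOBP_WIDTHS) {
    stop("SOBP width must be on the 30..100 mm by 10 mm grid", call. = FALSE)
  }
  if (is.null(pristine)) {
    pristine <- pristine_bragg_curve(energy, grid_spacing, const)
  }
  R <- pristine$nominal_range
  z_pk <- pristine$depths[which.max(pristine$values)]
  shifts <- seq(0, width, by = shift_step)
  # flat target from R - width up to the deepest peak's maximum (the
  # physical distal end of the modulation; beyond it the pristine falloff
  # takes over)
  ztarget <- seq(R - width, z_pk, by = grid_spacing)
  A <- vapply(shifts, function(s) curve_value(pristine, ztarget + s),
              numeric(length(ztarget)))
  w <- pracma::lsqnonneg(A, rep(1, length(ztarget)))$x
  w[w < 0] <- 0
  zmax <- max(pristine$depths)
  zout <- seq(0, zmax, by = grid_spacing)
  v <- numeric(length(zout))
  for (j in seq_along(shifts)) {
    if (w[j] > 0) v <- v + w[j] * curve_value(pristine, zout + shifts[j])
  }
  center <- R - width / 2
  vc <- approx(zout, v, xout = center)$y
  v <- v / vc
  w <- w / vc
  mod <- zout >= (R - width + 2) & zout <= (z_pk - 2)
  flat <- (max(v[mod]) - min(v[mod])) / mean(v[mod])
  if (flat > flatness_tol) {
    stop(sprintf("SOBP weight solve did not reach flatness tolerance: achieved %.3f%% > %.3f%%",
                 100 * flat, 100 * flatness_tol), call. = FALSE)
  }
  v[v < 1e-9] <- 0
  curve <- depth_dose_curve(zout, v, nominal_range = R, label = "sobp")
  structure(list(spec = sobp_spec(energy, width, shifts, w),
                 curve = curve, flatness = flat, pristine = pristine,
                 mod_region = c(R - width, z_pk)),
            class = "sobp")
}

#' @export
print.sobp <- function(x, ...) {
  cat(sprintf("<sobp: %g MeV, width %g mm, flatness %.2f%%, range %.1f mm>\n",
              x$spec$energy, x$spec$width, 100 * x$flatness,
              x$curve$nominal_range))
  invisible(x)
}

#' Flat-region bounds of a depth-dose curve
#'
#' Proximal and distal depths at which a (SOBP) curve crosses `level` times
#' its value at the SOBP center, found by linear interpolation. Used to
#' measure the realized modulation width.
#'
#' @param curve A [depth_dose_curve()].
#' @param level Fractional level, default 0.95.
#' @return `c(proximal, distal)` depths in mm.
#' @export
flat_region <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  v <- curve$values
  z <- curve$depths
  ipk <- which(v >= level)
  if (!length(ipk)) stop("curve never reaches the requested level", call. = FALSE)
  i1 <- min(ipk); i2 <- max(ipk)
  prox <- if (i1 == 1) z[1] else {
    approx(v[(i1 - 1):i1], z[(i1 - 1):i1], xout = level)$y
  }
  dist <- if (i2 == length(v)) z[i2] else {
    approx(v[i2:(i2 + 1)], z[i2:(i2 + 1)], xout = level)$y
  }
  c(proximal = prox, distal = dist)
}
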