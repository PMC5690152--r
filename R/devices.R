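# Patient-specific devices and phantom geometry.
#
# Coordinates: right-handed, origin at the isocenter, beam travels +z,
# devices at negative z. Lateral device coordinates are machined
# collimator-plane / compensator-plane coordinates.

#' Aperture collimator
#'
#' Patient-specific collimator opening described by an ordered closed polygon
#' of edge points in the collimator plane. Protons outside the opening are
#' terminated (the collimator is treated as perfectly absorbing; edge
#' scattering is not modelled and is corrected for downstream by the
#' field-size factor).
#'
#' @param edge_points Two-column matrix or data frame of (x, y) mm, the
#'   ordered vertices of the opening boundary. The polygon must be simple;
#'   the closing edge is implicit.
#' @param plane_distance Distance from the collimator plane to the isocenter
#'   (collimator-to-axis distance), mm.
#' @param thickness Physical thickness, mm (opaque; informational only).
#' @return An object of class `aperture_collimator`.
#' @export
aperture_collimator <- function(edge_points, plane_distance = 300,
                                thickness = 60) {
  ep <- as.matrix(edge_points)
  if (ncol(ep) != 2 || nrow(ep) < 3 || !is.numeric(ep)) {
    stop("edge_points must be a numeric matrix with >= 3 rows and 2 columns",
         call. = FALSE)
  }
  if (anyNA(ep)) stop("edge_points must not contain NA", call. = FALSE)
  # drop a duplicated closing vertex
  if (all(abs(ep[1, ] - ep[nrow(ep), ]) < 1e-12)) ep <- ep[-nrow(ep), , drop = FALSE]
  if (nrow(ep) < 3) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  if (.polygon_self_intersects(ep)) {
    stop("aperture polygon is self-intersecting", call. = FALSE)
  }
  stopifnot(plane_distance > 0, thickness > 0)
  ap <- structure(list(edge_points = unname(ep),
                       plane_distance = plane_distance, thickness = thickness),
                  class = "aperture_collimator")
  if (!point_in_aperture(ap, 0, 0)) {
    warning("aperture opening does not contain the beam axis (0, 0)", call. = FALSE)
  }
  ap
}

# segment intersection test over non-adjacent polygon edges (O(n^2); device
# polygons are small)
.polygon_self_intersects <- function(ep) {
  n <- nrow(ep)
  a <- ep
  b <- ep[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || j == i + 1 || (i == 1 && j == n)) next
      d1 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
      d2 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
      d3 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
      d4 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.aperture_collimator <- function(x, ...) {
  cat(sprintf("<aperture_collimator: %d edge points, plane %g mm, mean radius %.1f mm>\n",
              nrow(x$edge_points), x$plane_distance, mean_aperture_radius(x)))
  invisible(x)
}

#' Square and circular aperture constructors
#'
#' Convenience builders for the commissioning geometries: a centered square
#' opening of side `side` mm, and a circular opening sampled at
#' approximately 1 mm arc spacing.
#'
#' @param side Square side, mm.
#' @param plane_distance Collimator-to-axis distance, mm.
#' @param radius Circle radius, mm.
#' @param center Circle center (x, y), mm.
#' @param n_points Number of polygon vertices for the circle.
#' @return An [aperture_collimator()].
#' @export
square_aperture <- function(side, plane_distance = 300) {
  h <- side / 2
  # vertices at CT-like 1 mm spacing along the perimeter
  s <- seq(-h, h, length.out = max(2, ceiling(side) + 1))
  pts <- rbind(cbind(s, -h), cbind(h, s[-1]),
               cbind(rev(s)[-1], h), cbind(-h, rev(s)[-1]))
  pts <- pts[-nrow(pts), , drop = FALSE]
  aperture_collimator(pts, plane_distance = plane_distance)
}

#' @rdname square_aperture
#' @export
circular_aperture <- function(radius, plane_distance = 300, center = c(0, 0),
                              n_points = max(16, ceiling(2 * pi * radius))) {
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  aperture_collimator(cbind(center[1] + radius * cos(th),
                            center[2] + radius * sin(th)),
                      plane_distance = plane_distance)
}

#' Point-in-aperture predicate
#'
#' Even-odd (crossing number) polygon containment of lateral points in the
#' collimator plane. Points on the boundary count as inside (measure-zero
#' convention, fixed for determinism).
#'
#' @param aperture An [aperture_collimator()].
#' @param x,y Lateral coordinates, mm (vectorized).
#' @return Logical vector.
#' @export
point_in_aperture <- function(aperture, x, y) {
  stopifnot(inherits(aperture, "aperture_collimator"), length(x) == length(y))
  ep <- aperture$edge_points
  n <- nrow(ep)
  px <- ep[, 1]; py <- ep[, 2]
  qx <- ep[c(2:n, 1), 1]; qy <- ep[c(2:n, 1), 2]
  inside <- logical(length(x))
  on_edge <- logical(length(x))
  for (k in seq_len(n)) {
    crosses <- ((py[k] > y) != (qy[k] > y))
    if (any(crosses)) {
      xin <- px[k] + (y[crosses] - py[k]) * (qx[k] - px[k]) / (qy[k] - py[k])
      flip <- x[crosses] < xin
      inside[crosses] <- xor(inside[crosses], flip)
      on_edge[crosses][abs(x[crosses] - xin) < 1e-9] <- TRUE
    }
    # horizontal-edge / vertex boundary points
    dx <- qx[k] - px[k]; dy <- qy[k] - py[k]
    tt <- ((x - px[k]) * dx + (y - py[k]) * dy) / (dx^2 + dy^2)
    tt <- pmin(1, pmax(0, tt))
    d2 <- (px[k] + tt * dx - x)^2 + (py[k] + tt * dy - y)^2
    on_edge[d2 < 1e-18] <- TRUE
  }
  inside | on_edge
}

#' Mean aperture radius
#'
#' Mean Euclidean distance from the isocenter axis (0, 0) to the aperture
#' boundary, with the boundary resampled to uniform arc-length spacing
#' (default 1 mm, the planning-CT resolution) before averaging. This is the
#' scalar that indexes the field-size correction for irregular openings.
#'
#' @param aperture An [aperture_collimator()].
#' @param resample_spacing Arc-length spacing of the resampled boundary, mm.
#' @return Mean radius, mm.
#' @export
#' @examples
#' mean_aperture_radius(circular_aperture(50))   # 50
mean_aperture_radius <- function(aperture, resample_spacing = 1) {
  stopifnot(inherits(aperture, "aperture_collimator"), resample_spacing > 0)
  ep <- aperture$edge_points
  n <- nrow(ep)
  if (n < 1) stop("empty polygon", call. = FALSE)
  cl <- rbind(ep, ep[1, ])
  seg <- sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2)
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  s <- seq(0, total, by = resample_spacing)
  s <- s[s < total]
  xs <- approx(arc, cl[, 1], xout = s)$y
  ys <- approx(arc, cl[, 2], xout = s)$y
  mean(sqrt(xs^2 + ys^2))
}

#' Range compensator
#'
#' Patient-specific variable-thickness device given as a 2-D lateral map of
#' physical thickness on a uniform grid.
#'
#' @param thickness Numeric matrix of physical thickness, mm, >= 0; rows
#'   index x, columns index y.
#' @param origin (x, y) of the first grid node, mm.
#' @param spacing Grid spacing, mm, <= 2.
#' @param wel_ratio Water-equivalent thickness ratio of the material.
#' @param plane_distance Distance of the compensator plane from the
#'   isocenter, mm.
#' @return An object of class `range_compensator`.
#' @export
range_compensator <- function(thickness, origin = NULL, spacing = 2,
                              wel_ratio = 1.0, plane_distance = 330) {
  thickness <- as.matrix(thickness)
  stopifnot(is.numeric(thickness), spacing > 0, wel_ratio > 0, plane_distance > 0)
  if (spacing > 2 + 1e-9) stop("compensator grid spacing must be <= 2 mm", call. = FALSE)
  if (any(thickness < 0)) stop("compensator thickness must be >= 0", call. = FALSE)
  if (is.null(origin)) {
    origin <- -spacing * (dim(thickness) - 1) / 2   # centered on the axis
  }
  structure(list(thickness = unname(thickness), origin = as.numeric(origin),
                 spacing = spacing, wel_ratio = wel_ratio,
                 plane_distance = plane_distance),
            class = "range_compensator")
}

#' Uniform slab compensator
#'
#' @param thickness Uniform physical thickness, mm.
#' @param halfwidth Lateral half-extent of the map, mm.
#' @param ... Passed to [range_compensator()].
#' @return A [range_compensator()].
#' @export
uniform_compensator <- function(thickness, halfwidth = 150, ...) {
  n <- ceiling(halfwidth) + 1
  range_compensator(matrix(thickness, 2 * n - 1, 2 * n - 1),
                    origin = c(-(n - 1), -(n - 1)), spacing = 1, ...)
}

#' @export
print.range_compensator <- function(x, ...) {
  cat(sprintf("<range_compensator: %dx%d grid @ %g mm, thickness %.1f-%.1f mm, WELR %.3f>\n",
              nrow(x$thickness), ncol(x$thickness), x$spacing,
              min(x$thickness), max(x$thickness), x$wel_ratio))
  invisible(x)
}

#' Water-equivalent compensator thickness at a lateral point
#'
#' Bilinear interpolation of the physical thickness map times the material's
#' WEL ratio. Queries outside the grid extent are clamped to the nearest
#' edge of the map (fails safe toward the edge thickness).
#'
#' @param comp A [range_compensator()].
#' @param x,y Lateral coordinates, mm (vectorized).
#' @return Water-equivalent thickness, mm.
#' @export
compensator_thickness_at <- function(comp, x, y) {
  stopifnot(inherits(comp, "range_compensator"), length(x) == length(y))
  nx <- nrow(comp$thickness); ny <- ncol(comp$thickness)
  u <- (x - comp$origin[1]) / comp$spacing
  v <- (y - comp$origin[2]) / comp$spacing
  u <- pmin(pmax(u, 0), nx - 1)
  v <- pmin(pmax(v, 0), ny - 1)
  i0 <- pmin(floor(u), nx - 2); j0 <- pmin(floor(v), ny - 2)
  i0[nx == 1] <- 0; j0[ny == 1] <- 0
  fu <- u - i0; fv <- v - j0
  th <- comp$thickness
  idx <- function(i, j) th[cbind(i + 1, j + 1)]
  val <- (1 - fu) * (1 - fv) * idx(i0, j0) +
    fu * (1 - fv) * idx(pmin(i0 + 1, nx - 1), j0) +
    (1 - fu) * fv * idx(i0, pmin(j0 + 1, ny - 1)) +
    fu * fv * idx(pmin(i0 + 1, nx - 1), pmin(j0 + 1, ny - 1))
  val * comp$wel_ratio
}

#' Range shifter
#'
#' Binary slab stack reducing the beam range by a set water-equivalent
#' thickness between 0 and 120 mm WEL.
#'
#' @param thickness Thickness in mm WEL.
#' @return An object of class `range_shifter`.
#' @export
range_shifter <- function(thickness) {
  stopifnot(is.numeric(thickness), length(thickness) == 1)
  if (thickness < 0 || thickness > 120) {
    stop("range shifter thickness must be in [0, 120] mm WEL", call. = FALSE)
  }
  structure(list(thickness = thickness), class = "range_shifter")
}

#' Uniform phantom
#'
#' Water-equivalent phantom with 2 mm isotropic voxels, laterally infinite
#' for transport purposes (only the scoring grid is bounded).
#'
#' @param entrance_z z of the entrance surface, mm (negative: upstream of
#'   the isocenter).
#' @param wel_ratio Uniform water-equivalent thickness ratio.
#' @param voxel Voxel size, mm (2 mm, the engine's scoring resolution).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(entrance_z, wel_ratio = 1.0, voxel = 2) {
  stopifnot(wel_ratio > 0, voxel > 0)
  if (entrance_z > 0) stop("phantom entrance must not be downstream of the isocenter",
                           call. = FALSE)
  structure(list(entrance_z = entrance_z, wel_ratio = wel_ratio, voxel = voxel),
            class = "phantom_spec")
}

#' Phantom thickness placing the detector at the SOBP center
#'
#' Physical phantom thickness that puts the measurement point at the center
#' of the SOBP: `(range - sobp/2 - rs) / welr`.
#'
#' @param range Beam range, mm WEL.
#' @param sobp SOBP width, mm WEL.
#' @param rs Range shifter thickness, mm WEL.
#' @param welr Water-equivalent thickness ratio of the phantom.
#' @return Physical thickness, mm.
#' @export
#' @examples
#' phantom_depth_for_sobp_center(200, 80, 0, 1.0)   # 160
phantom_depth_for_sobp_center <- function(range, sobp, rs, welr) {
  stopifnot(range >= 0, sobp >= 0, rs >= 0, welr > 0)
  d <- (range - sobp / 2 - rs) / welr
  if (d < 0) {
    stop("beam cannot reach the measurement depth (range - sobp/2 - rs < 0)",
         call. = FALSE)
  }
  d
}

# ---- device file I/O --------------------------------------------------------

#' Aperture and compensator file I/O
#'
#' Aperture: CSV of ordered `(x_mm, y_mm)` pairs with one leading header line
#' carrying `plane_distance_mm`. Compensator: CSV thickness matrix plus a
#' JSON sidecar (`<path>.json`) with origin, spacing, WEL ratio and plane
#' distance.
#'
#' @param aperture An [aperture_collimator()].
#' @param comp A [range_compensator()].
#' @param path File path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_aperture <- function(aperture, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("plane_distance_mm,%.17g", aperture$plane_distance), con)
  writeLines("x_mm,y_mm", con)
  writeLines(sprintf("%.17g,%.17g",
                     aperture$edge_points[, 1], aperture$edge_points[, 2]), con)
  invisible(path)
}

#' @rdname write_aperture
#' @export
read_aperture <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (hdr[1] != "plane_distance_mm") stop("malformed aperture file", call. = FALSE)
  df <- read.csv(path, skip = 1L)
  aperture_collimator(cbind(df$x_mm, df$y_mm),
                      plane_distance = as.numeric(hdr[2]))
}

#' @rdname write_aperture
#' @export
write_compensator <- function(comp, path) {
  write.table(format(comp$thickness, digits = 17, trim = TRUE, scientific = TRUE),
              file = path, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  meta <- list(origin_mm = comp$origin, spacing_mm = comp$spacing,
               wel_ratio = comp$wel_ratio, plane_distance_mm = comp$plane_distance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aperture
#' @export
read_compensator <- function(path) {
  th <- as.matrix(read.csv(path, header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  range_compensator(th, origin = meta$origin_mm, spacing = meta$spacing_mm,
                    wel_ratio = meta$wel_ratio,
                    plane_distance = meta$plane_distance_mm)
}
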