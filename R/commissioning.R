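# Synthetic commissioning data: beam-spreading-device factor table,
# measured field-size curves, effective source, and the bundled
# commissioning object used by the DMU pipeline.

#' Beam-spreading-device factor table
#'
#' Long-format table of the factor F_BSD on the commissioning grid
#' (energy x SOBP width x range-shifter thickness), normalized to 1 at the
#' standard condition (190 MeV, 80 mm SOBP, 0 mm RS).
#'
#' @param df Data frame with columns `energy_mev`, `sobp_mm`, `rs_mm_wel`,
#'   `value`.
#' @return An object of class `fbsd_table` (a data frame).
#' @export
fbsd_table <- function(df) {
  need <- c("energy_mev", "sobp_mm", "rs_mm_wel", "value")
  if (!all(need %in% names(df))) {
    stop("fbsd_table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(df$value <= 0)) stop("F_BSD values must be > 0", call. = FALSE)
  std <- df$value[df$energy_mev == 190 & df$sobp_mm == 80 & df$rs_mm_wel == 0]
  if (length(std) != 1 || abs(std - 1) > 1e-12) {
    stop("F_BSD must be exactly 1 at the standard condition (190 MeV, 80 mm, 0 mm RS)",
         call. = FALSE)
  }
  # monotonicity: non-increasing in RS at fixed (energy, width), and in
  # width at fixed (energy, RS)
  sp <- split(df, list(df$energy_mev, df$sobp_mm), drop = TRUE)
  for (g in sp) {
    g <- g[order(g$rs_mm_wel), ]
    if (any(diff(g$value) > 1e-12)) {
      stop("F_BSD must be non-increasing in RS thickness", call. = FALSE)
    }
  }
  sp <- split(df, list(df$energy_mev, df$rs_mm_wel), drop = TRUE)
  for (g in sp) {
    g <- g[order(g$sobp_mm), ]
    if (any(diff(g$value) > 1e-12)) {
      stop("F_BSD must be non-increasing in SOBP width", call. = FALSE)
    }
  }
  structure(as.data.frame(df), class = c("fbsd_table", "data.frame"))
}

#' Generate a synthetic F_BSD table
#'
#' Smooth separable parametric stand-in for the measured beam-spreading
#' device factor: `F = base_E * exp(-a_E * rs - b_E * (width - 80))`, with
#' per-energy scale `base_E` and positive decay rates `a_E` (per mm RS) and
#' `b_E` (per mm SOBP width). The seed applies a small (+-5%) reproducible
#' perturbation to the decay rates, leaving the required monotonicities and
#' the standard-condition normalization intact. Absolute values are fixture
#' conventions, not physics claims; only the trends (decreasing in RS
#' thickness and SOBP width) emulate commissioning data.
#'
#' The RS grid per (energy, width) runs from 0 in steps of 10 mm WEL
#' (20 mm for widths >= 70 mm) up to at most 120 mm WEL, truncated so the
#' beam still reaches the SOBP-center measurement depth.
#'
#' @param seed Integer seed; generation is bit-for-bit reproducible.
#' @param const A [beam_constants()] object.
#' @return An [fbsd_table()].
#' @export
#' @examples
#' tab <- generate_fbsd_table(seed = 1)
#' subset(tab, energy_mev == 190 & sobp_mm == 80 & rs_mm_wel == 0)$value  # 1
generate_fbsd_table <- function(seed = 1L, const = beam_constants()) {
  base <- c(`150` = 0.94, `190` = 1.00, `235` = 1.07)
  a0 <- c(`150` = 0.0026, `190` = 0.0022, `235` = 0.0018)
  b0 <- c(`150` = 0.0016, `190` = 0.0014, `235` = 0.0012)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  jit_a <- 1 + 0.05 * runif(3, -1, 1)
  jit_b <- 1 + 0.05 * runif(3, -1, 1)
  rows <- list()
  for (i in seq_along(BEAM_ENERGIES)) {
    e <- BEAM_ENERGIES[i]
    key <- as.character(e)
    a <- a0[[key]] * jit_a[i]
    b <- b0[[key]] * jit_b[i]
    R <- range_from_energy(e, const)
    for (w in SOBP_WIDTHS) {
      step <- if (w >= 70) 20 else 10
      rs_max <- min(120, max(0, floor((R - w - 40) / step) * step))
      rs <- seq(0, rs_max, by = step)
      rows[[length(rows) + 1]] <- data.frame(
        energy_mev = e, sobp_mm = w, rs_mm_wel = rs,
        value = base[[key]] * exp(-a * rs - b * (w - 80)))
    }
  }
  fbsd_table(do.call(rbind, rows))
}

#' Field-size table
#'
#' Output factor versus square aperture side for one beam energy,
#' normalized to 1 at the 185 mm standard square.
#'
#' @param energy Beam energy, MeV.
#' @param aperture_sides Square sides, mm.
#' @param f_values Factors; must satisfy `f(185) = 1` and `0 < f <= 1.01`.
#' @param kind `"measured"` or `"calculated"` (informational).
#' @return An object of class `field_size_table`.
#' @export
field_size_table <- function(energy, aperture_sides, f_values,
                             kind = c("measured", "calculated")) {
  kind <- match.arg(kind)
  stopifnot(length(aperture_sides) == length(f_values))
  o <- order(aperture_sides)
  aperture_sides <- aperture_sides[o]
  f_values <- f_values[o]
  if (!any(aperture_sides == 185)) {
    stop("field-size table must include the 185 mm normalization square", call. = FALSE)
  }
  if (abs(f_values[aperture_sides == 185] - 1) > 1e-12) {
    stop("f(185) must be exactly 1", call. = FALSE)
  }
  if (any(f_values <= 0 | f_values > 1.01)) {
    stop("field-size factors must be in (0, 1.01]", call. = FALSE)
  }
  structure(list(energy = energy, aperture_sides = aperture_sides,
                 f_values = f_values, kind = kind),
            class = "field_size_table")
}

#' @export
print.field_size_table <- function(x, ...) {
  cat(sprintf("<field_size_table (%s): %g MeV>\n", x$kind, x$energy))
  print(setNames(round(x$f_values, 4), x$aperture_sides))
  invisible(x)
}

#' Synthetic measured field-size curves
#'
#' Deterministic parametric stand-in for the measured aperture-size
#' dependence of the output: a smooth exponential approach to 1,
#' `f(A) = 1 - D * (g(A) - g(185)) / (g(40) - g(185))` with
#' `g(A) = exp(-(A - 40)/40)`. The depth of the effect is `D = 0.05` at
#' 235 MeV (a 5% falloff from the 185 mm to the 40 mm square) and
#' `D = 0.008` at 150 and 190 MeV (a sub-1% effect), emulating the measured
#' trends.
#'
#' @param energy One of 150, 190, 235 MeV.
#' @param aperture_sides Square sides to tabulate, mm.
#' @return A [field_size_table()] with `kind = "measured"`.
#' @export
#' @examples
#' tab <- generate_fmeas_fs_table(235)
#' 100 * (1 - tab$f_values[tab$aperture_sides == 40])   # 5
generate_fmeas_fs_table <- function(energy, aperture_sides = FS_APERTURE_SIDES) {
  if (!energy %in% BEAM_ENERGIES) {
    stop("energy must be one of ", paste(BEAM_ENERGIES, collapse = ", "), call. = FALSE)
  }
  depth <- if (energy == 235) 0.05 else 0.008
  g <- function(a) exp(-(a - 40) / 40)
  f <- 1 - depth * (g(aperture_sides) - g(185)) / (g(40) - g(185))
  f[aperture_sides == 185] <- 1   # exact normalization
  field_size_table(energy, aperture_sides, f, kind = "measured")
}

#' Gaussian effective source
#'
#' Single-Gaussian effective-source model of everything upstream of the
#' patient-specific devices: a virtual source on the axis at
#' `source_to_axis_distance` upstream of the isocenter, with Gaussian
#' lateral position blur `lateral_sigma` and Gaussian angular spread
#' `angular_sigma` about the aiming ray. The default parameters are
#' declared fixture values (the facility values are set by measurement).
#' `source_to_axis_distance = Inf` gives a parallel beam; zero sigmas give
#' the degenerate pencil limit.
#'
#' @param source_to_axis_distance mm; may be `Inf` for a parallel beam.
#' @param lateral_sigma mm, >= 0.
#' @param angular_sigma radian, >= 0.
#' @return An object of class `effective_source`.
#' @export
effective_source <- function(source_to_axis_distance = 2000,
                             lateral_sigma = 10, angular_sigma = 0.003) {
  stopifnot(source_to_axis_distance > 0, lateral_sigma >= 0, angular_sigma >= 0)
  structure(list(sad = as.numeric(source_to_axis_distance),
                 lateral_sigma = as.numeric(lateral_sigma),
                 angular_sigma = as.numeric(angular_sigma)),
            class = "effective_source")
}

#' Synthesize a full commissioning data set
#'
#' Bundles everything the DMU pipeline needs: beam-model constants, the
#' effective source, pristine Bragg curves for the three energies, the
#' synthetic F_BSD table and the synthetic measured field-size curves.
#' SOBPs are built on demand from the pristine curves.
#'
#' @param seed Integer seed (drives the F_BSD parameter jitter).
#' @param grid_spacing Depth-dose grid spacing, mm.
#' @param const A [beam_constants()] object.
#' @param source An [effective_source()].
#' @return An object of class `commissioning`.
#' @export
#' @examples
#' comm <- synthesize_commissioning(seed = 1)
synthesize_commissioning <- function(seed = 1L, grid_spacing = 0.5,
                                     const = beam_constants(),
                                     source = effective_source()) {
  pristine <- lapply(BEAM_ENERGIES, pristine_bragg_curve,
                     grid_spacing = grid_spacing, const = const)
  names(pristine) <- as.character(BEAM_ENERGIES)
  fs <- lapply(BEAM_ENERGIES, generate_fmeas_fs_table)
  names(fs) <- as.character(BEAM_ENERGIES)
  structure(list(const = const, source = source, grid_spacing = grid_spacing,
                 pristine = pristine,
                 fbsd = generate_fbsd_table(seed, const),
                 fmeas_fs = fs, seed = as.integer(seed),
                 sobp_cache = new.env(parent = emptyenv())),
            class = "commissioning")
}

#' @export
print.commissioning <- function(x, ...) {
  cat(sprintf("<commissioning: energies %s MeV, %d F_BSD rows, seed %d>\n",
              paste(BEAM_ENERGIES, collapse = "/"), nrow(x$fbsd), x$seed))
  invisible(x)
}

#' SOBP for a commissioning bundle
#'
#' Returns the [build_sobp()] result for `(energy, width)`, built from the
#' bundle's pristine curve and cached inside the bundle.
#'
#' @param comm A commissioning bundle.
#' @param energy Beam energy, MeV.
#' @param width SOBP width, mm.
#' @return An object of class `sobp`.
#' @export
commissioning_sobp <- function(comm, energy, width) {
  key <- sprintf("%g_%g", energy, width)
  if (!is.null(comm$sobp_cache[[key]])) return(comm$sobp_cache[[key]])
  s <- build_sobp(energy, width, grid_spacing = comm$grid_spacing,
                  const = comm$const,
                  pristine = comm$pristine[[as.character(energy)]])
  comm$sobp_cache[[key]] <- s
  s
}

# ---- commissioning table I/O -----------------------------------------------

#' Commissioning table I/O
#'
#' F_BSD tables are CSV with columns `energy_mev, sobp_mm, rs_mm_wel, value`;
#' field-size tables are CSV with `energy_mev, aperture_side_mm, f_value`.
#' [write_commissioning()] writes a whole bundle (curves, tables, source and
#' constants) into a directory that [read_commissioning()] reconstructs.
#'
#' @param tab Table object.
#' @param path,dir File / directory path.
#' @param comm A `commissioning` object.
#' @return Readers return the object; writers return the path invisibly.
#' @export
write_fbsd_table <- function(tab, path) {
  stopifnot(inherits(tab, "fbsd_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("energy_mev,sobp_mm,rs_mm_wel,value", con)
  writeLines(sprintf("%.17g,%.17g,%.17g,%.17g", tab$energy_mev, tab$sobp_mm,
                     tab$rs_mm_wel, tab$value), con)
  invisible(path)
}

#' @rdname write_fbsd_table
#' @export
read_fbsd_table <- function(path) {
  df <- read.csv(path)
  df[] <- lapply(df, as.numeric)
  fbsd_table(df)
}

#' @rdname write_fbsd_table
#' @export
write_field_size_table <- function(tab, path) {
  stopifnot(inherits(tab, "field_size_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", tab$kind), con)
  writeLines("energy_mev,aperture_side_mm,f_value", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", tab$energy, tab$aperture_sides,
                     tab$f_values), con)
  invisible(path)
}

#' @rdname write_fbsd_table
#' @export
read_field_size_table <- function(path) {
  kind <- sub("^# kind=", "", readLines(path, n = 1L))
  df <- read.csv(path, skip = 1L)
  field_size_table(as.numeric(df$energy_mev[1]), as.numeric(df$aperture_side_mm),
                   as.numeric(df$f_value), kind = kind)
}

#' @rdname write_fbsd_table
#' @export
write_commissioning <- function(comm, dir) {
  stopifnot(inherits(comm, "commissioning"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in names(comm$pristine)) {
    write_depth_dose_curve(comm$pristine[[e]],
                           file.path(dir, sprintf("pristine_%s.csv", e)))
  }
  write_fbsd_table(comm$fbsd, file.path(dir, "fbsd.csv"))
  for (e in names(comm$fmeas_fs)) {
    write_field_size_table(comm$fmeas_fs[[e]],
                           file.path(dir, sprintf("fmeas_fs_%s.csv", e)))
  }
  jsonlite::write_json(
    list(seed = comm$seed, grid_spacing = comm$grid_spacing,
         const = unclass(comm$const),
         source = unclass(comm$source)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_fbsd_table
#' @export
read_commissioning <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  const <- do.call(beam_constants, as.list(meta$const))
  source <- effective_source(meta$source$sad, meta$source$lateral_sigma,
                             meta$source$angular_sigma)
  pristine <- lapply(as.character(BEAM_ENERGIES), function(e) {
    read_depth_dose_curve(file.path(dir, sprintf("pristine_%s.csv", e)))
  })
  names(pristine) <- as.character(BEAM_ENERGIES)
  fs <- lapply(as.character(BEAM_ENERGIES), function(e) {
    read_field_size_table(file.path(dir, sprintf("fmeas_fs_%s.csv", e)))
  })
  names(fs) <- as.character(BEAM_ENERGIES)
  structure(list(const = const, source = source,
                 grid_spacing = meta$grid_spacing, pristine = pristine,
                 fbsd = read_fbsd_table(file.path(dir, "fbsd.csv")),
                 fmeas_fs = fs, seed = as.integer(meta$seed),
                 sobp_cache = new.env(parent = emptyenv())),
            class = "commissioning")
}
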