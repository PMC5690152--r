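# Shared fixtures: one commissioning bundle per source geometry, memoised
# across test files (SOBP builds are cached inside the bundle).

comm_default <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- synthesize_commissioning(seed = 1)
    val
  }
})

# parallel, zero-emittance beam for geometric checks
comm_parallel <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- synthesize_commissioning(seed = 1,
                                       source = effective_source(Inf, 0, 0))
    }
    val
  }
})

# laterally integrated depth-dose profile and its distal 80% position
distal80 <- function(grid) {
  idd <- integrated_depth_dose(grid)
  pk <- max(idd$dose)
  i <- max(which(idd$dose >= 0.8 * pk))
  approx(idd$dose[i:(i + 1)], idd$depth_wel[i:(i + 1)], xout = 0.8 * pk)$y
}

# independent ray-casting point-in-polygon oracle (pracma)
pip_oracle <- function(poly, x, y) {
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

# build a dose_grid-shaped object from an array, for analytic field tests
fake_grid <- function(arr, origin = c(0, 0, 0), vox = 2, n_protons = 1,
                      batch_dose = NULL, batch_index = NULL, n_batches = NULL) {
  structure(list(dose = arr, origin = origin, vox = vox, dims = dim(arr),
                 n_protons = n_protons, phantom_welr = 1,
                 batch_dose = batch_dose, batch_index = batch_index,
                 n_batches = n_batches),
            class = "dose_grid")
}

# fill a grid with an analytic function of the voxel-center coordinates
analytic_grid <- function(f, dims = c(21, 21, 21), origin = c(-21, -21, -21),
                          vox = 2) {
  x <- origin[1] + (seq_len(dims[1]) - 0.5) * vox
  y <- origin[2] + (seq_len(dims[2]) - 0.5) * vox
  z <- origin[3] + (seq_len(dims[3]) - 0.5) * vox
  arr <- array(0, dims)
  A <- outer(x, rep(1, dims[2]))
  B <- outer(rep(1, dims[1]), y)
  for (k in seq_len(dims[3])) {
    arr[, , k] <- f(A, B, z[k]) + 0 * A
  }
  fake_grid(arr, origin = origin, vox = vox)
}
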