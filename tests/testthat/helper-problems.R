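# Shared fixtures.  Expensive objects (default-size controller run,
# influence matrix) are computed once per test session and memoized, since
# several acceptance criteria read the same run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# A reduced problem (coarser grid, fewer beams) with the same physical
# extent as the default; used by tests that need many optimizer or
# controller runs.
small_phantom <- function(seed = 1L, laterality = "left") {
  generate_phantom(phantom_config(laterality, grid_shape = c(64L, 64L),
                                  spacing_mm = 6), seed = seed)
}

small_problem <- function(seed = 1L, laterality = "left") {
  key <- sprintf("small_%s_%d", laterality, seed)
  memo(key, {
    ph <- small_phantom(seed, laterality)
    bs <- build_beamset(ph, n_angles = 10L, beamlets_per_angle = 12L)
    list(phantom = ph, beamset = bs,
         influence = compute_influence(ph, bs))
  })
}

# The default study conditions: 128x128 grid at 3 mm, 28 angles, default
# controller settings, seed 1.
default_phantom <- function() {
  memo("default_phantom", generate_phantom(phantom_config(), seed = 1L))
}

default_beamset <- function() {
  memo("default_beamset", build_beamset(default_phantom()))
}

default_influence <- function() {
  memo("default_influence",
       compute_influence(default_phantom(), default_beamset()))
}

# Full controller run on the default problem, with wall-clock time attached
# (attribute "elapsed_s").
default_run <- function() {
  memo("default_run", {
    t0 <- Sys.time()
    run <- run_controller(default_phantom(), default_beamset(),
                          controller_config(),
                          influence = default_influence())
    attr(run, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs"))
    run
  })
}

# A tiny dense influence for gradient and optimizer oracles: n_vox voxels,
# n_beam beamlets, random positive entries.
toy_influence <- function(n_row = 6L, n_col = 6L, n_beam = 4L, seed = 42L) {
  set.seed(seed)
  n_vox <- n_row * n_col
  A <- Matrix::Matrix(matrix(stats::runif(n_vox * n_beam, 0, 0.4),
                             n_vox, n_beam), sparse = TRUE)
  structure(list(A = A, At = Matrix::t(A), grid_shape = c(n_row, n_col),
                 n_beamlets = n_beam,
                 beamlet_index = data.frame(beamlet = seq_len(n_beam),
                                            angle_deg = 0, offset_mm = 0),
                 attenuation = 0.005, lateral_sigma = 3,
                 scatter_fraction = 0, scatter_sigma = 24),
            class = "ofv_influence")
}

# A minimal phantom-like object carrying only masks, for objective tests on
# toy grids.
toy_phantom <- function(n_row = 6L, n_col = 6L) {
  full <- matrix(TRUE, n_row, n_col)
  top <- matrix(FALSE, n_row, n_col); top[seq_len(n_row %/% 2), ] <- TRUE
  structure(list(grid_shape = c(n_row, n_col), spacing_mm = 3,
                 slice_thickness_mm = 3, laterality = "left", seed = 0L,
                 masks = list(PTV = top, external = full, OAR = !top),
                 voxel_volume_cm3 = 0.027),
            class = "ofv_phantom")
}
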