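#' Mono-exponential echo-time signal model
#'
#' Gradient-echo signal magnitude at echo time `te_ms` for a compartment
#' with amplitude `s0` and effective relaxation time `t2star_ms`:
#' `s0 * exp(-te_ms / t2star_ms)`. This is the standard T2* decay model
#' underlying BOLD-weighted EPI contrast.
#'
#' @param s0 amplitude at TE = 0, >= 0 (vectorized).
#' @param t2star_ms effective T2* in ms, > 0 (vectorized).
#' @param te_ms echo time in ms, >= 0 (vectorized).
#' @return Signal magnitude(s).
#' @examples
#' signal_te(100, 50, 50)  # 100 / e
#' @export
signal_te <- function(s0, t2star_ms, te_ms) {
  if (any(t2star_ms <= 0)) {
    abort("`t2star_ms` must be > 0", class = "fetaltrack_argument_error")
  }
  if (any(s0 < 0) || any(te_ms < 0)) {
    abort("`s0` and `te_ms` must be >= 0", class = "fetaltrack_argument_error")
  }
  s0 * exp(-te_ms / t2star_ms)
}

#' Acquisition configuration for the simulated scanner
#'
#' Defaults mirror the phantom protocol the closed loop is evaluated on:
#' 3.0 mm isotropic voxels, 50 repetitions, TE = 90 ms. The grid edge
#' defaults to 64 voxels (192 mm FOV extent at 3 mm). `noise_sigma` is the
#' standard deviation of additive Gaussian noise in the image domain, in
#' the same arbitrary units as `s0`; each repetition draws from an
#' independent stream seeded with `seed + repetition`.
#'
#' @param edge voxels per axis of the acquisition grid.
#' @param spacing_mm isotropic voxel spacing in mm.
#' @param te_ms echo time(s) in ms; multi-echo series list several.
#' @param n_repetitions number of repetitions in the dynamic series.
#' @param noise_sigma additive Gaussian noise sd (image domain), >= 0.
#' @param seed base integer seed for the noise streams.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(edge = 64L, spacing_mm = 3.0, te_ms = 90,
                               n_repetitions = 50L, noise_sigma = 0,
                               seed = 1L) {
  te_ms <- as.numeric(te_ms)
  if (length(te_ms) == 0 || any(te_ms <= 0)) {
    abort("`te_ms` must be a non-empty vector of positive echo times",
          class = "fetaltrack_argument_error")
  }
  if (noise_sigma < 0) {
    abort("`noise_sigma` must be >= 0", class = "fetaltrack_argument_error")
  }
  structure(list(edge = as.integer(edge), spacing_mm = as.numeric(spacing_mm),
                 te_ms = te_ms, n_repetitions = as.integer(n_repetitions),
                 noise_sigma = as.numeric(noise_sigma), seed = as.integer(seed)),
            class = "acquisition_config")
}

acq_geometry <- function(config, fov_center = c(0, 0, 0)) {
  grid_geometry(rep(config$edge, 3L), rep(config$spacing_mm, 3L), fov_center)
}

#' Simulate the acquisition of one repetition
#'
#' Forms the EPI-like magnitude image of a [world_scene()] at the
#' controller's current FOV: each voxel takes the [signal_te()] value of the
#' scene component occupying its world-space center (the tracked target
#' displaced by the trajectory offset of this repetition; later components
#' overwrite earlier ones), plus seeded Gaussian noise. Purely geometric
#' rasterization — no k-space, distortion or ghosting model — matching what
#' a magnitude-image tracking loop actually consumes.
#'
#' @param scene a [world_scene()].
#' @param trajectory a trajectory from [step_trajectory()].
#' @param fov a [grid_geometry()]; its `fov_center` is the controller state.
#' @param repetition 1-based repetition index, within the trajectory.
#' @param te_ms echo time for this volume (default: first configured TE).
#' @param config an [acquisition_config()].
#' @return A [volume_grid()]; deterministic for fixed (seed, repetition, TE).
#' @export
acquire_repetition <- function(scene, trajectory, fov, repetition,
                               te_ms = config$te_ms[1], config) {
  stopifnot(inherits(scene, "world_scene"), inherits(fov, "grid_geometry"))
  offset <- trajectory_offset(trajectory, repetition)
  vals <- array(signal_te(scene$background_s0, scene$background_t2star_ms, te_ms),
                dim = fov$shape)
  for (i in seq_along(scene$components)) {
    comp <- scene$components[[i]]
    off_i <- if (i == scene$target_index) offset else c(0, 0, 0)
    inside <- component_inside(comp, fov, off_i)
    vals[inside] <- signal_te(comp$s0, comp$t2star_ms, te_ms)
  }
  if (config$noise_sigma > 0) {
    # independent, reproducible stream per repetition
    vals <- vals + with_preserved_seed({
      set.seed((config$seed + repetition) %% .Machine$integer.max)
      array(rnorm(length(vals), 0, config$noise_sigma), dim = dim(vals))
    })
    vals[vals < 0] <- 0
  }
  volume_grid(vals, fov, repetition = repetition, te_ms = te_ms)
}

#' Ground-truth mask of the tracked target
#'
#' Rasterizes the displaced target component on the given FOV: a voxel is
#' foreground iff its center lies inside the target. Stands in for manually
#' drawn gold-standard masks in synthetic experiments.
#'
#' @inheritParams acquire_repetition
#' @return A [binary_mask()].
#' @export
analytic_target_mask <- function(scene, trajectory, fov, repetition) {
  stopifnot(inherits(scene, "world_scene"), inherits(fov, "grid_geometry"))
  offset <- trajectory_offset(trajectory, repetition)
  comp <- scene$components[[scene$target_index]]
  binary_mask(component_inside(comp, fov, offset), fov)
}

#' Write a simulated dynamic series to disk
#'
#' Acquires all repetitions of a scene/trajectory at a fixed FOV and writes
#' a 4D NIfTI plus the ground-truth trajectory as CSV (columns repetition,
#' dx_mm, dy_mm, dz_mm).
#'
#' @inheritParams acquire_repetition
#' @param path_nii output path for the 4D NIfTI.
#' @param path_csv output path for the trajectory CSV (`NULL` to skip).
#' @param fov_center world FOV center used for the whole series.
#' @return Invisibly, the list of acquired [volume_grid()]s.
#' @export
simulate_series <- function(scene, trajectory, config, path_nii,
                            path_csv = NULL, fov_center = c(0, 0, 0)) {
  fov <- acq_geometry(config, fov_center)
  vols <- lapply(seq_len(trajectory$n_repetitions), function(r) {
    acquire_repetition(scene, trajectory, fov, r, config$te_ms[1], config)
  })
  save_volume(vols, path_nii)
  if (!is.null(path_csv)) {
    write.csv(tidy(trajectory), path_csv, row.names = FALSE)
  }
  invisible(vols)
}

# run expr with the global RNG state saved and restored
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
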