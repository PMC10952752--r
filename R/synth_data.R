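#' Generate synthetic fetal-head training scenes
#'
#' Draws independent fetal-head-like scenes ([make_fetal_world()]) and
#' renders each once with the simulated acquisition: an axis-aligned
#' ellipsoidal head of randomized size (half-axes around 26-34 mm, the
#' scale of a mid-gestation fetal head), position and amplitude, a
#' confounding high-signal blob (radius 10-16 mm, the "stomach" failure
#' mode) at a random offset, dim maternal-tissue background, and additive
#' Gaussian noise. Echo time and voxel spacing default to the dynamic EPI
#' protocol the tracking loop targets (TE 90 ms, 3 mm isotropic).
#'
#' Ground truth is the analytic head mask. Each sample is a list with
#' `volume` (a [volume_grid()]), `mask` (a [binary_mask()]) and `scene`.
#'
#' @param n number of scenes.
#' @param edge grid edge in voxels.
#' @param spacing_mm isotropic voxel spacing in mm.
#' @param te_ms echo time in ms.
#' @param noise_sigma image-domain Gaussian noise sd (signal units; the
#'   head renders near 22 at the defaults).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of it.
#' @return List of `n` samples.
#' @export
synth_head_dataset <- function(n, edge = 64L, spacing_mm = 3.0, te_ms = 90,
                               noise_sigma = 5, seed = 0L) {
  with_preserved_seed({
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      a <- runif(1, 26, 34)
      radii <- c(a, a * runif(1, 0.75, 0.95), a * runif(1, 0.75, 0.95))
      half_extent <- edge * spacing_mm / 2
      lim <- half_extent - max(radii) - 2 * spacing_mm
      head_center <- runif(3, -min(lim, 24), min(lim, 24))
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      conf_r <- runif(1, 10, 16)
      conf_center <- head_center + dir * runif(1, 55, 75)
      conf_center <- pmin(pmax(conf_center, -half_extent + conf_r),
                          half_extent - conf_r)
      scene <- make_fetal_world(
        head_radii_mm = radii,
        head_center = head_center,
        confounder = scene_component("sphere", conf_center, conf_r,
                                     s0 = 100 * runif(1, 0.9, 1.1),
                                     t2star_ms = 80),
        background_s0 = 20,
        s0 = 100 * runif(1, 0.9, 1.1)
      )
      cfg <- acquisition_config(edge = edge, spacing_mm = spacing_mm,
                                te_ms = te_ms, n_repetitions = 1L,
                                noise_sigma = noise_sigma,
                                seed = sample.int(2^30, 1))
      traj <- step_trajectory(list(), 1L)
      fov <- acq_geometry(cfg)
      list(volume = acquire_repetition(scene, traj, fov, 1L, te_ms, cfg),
           mask = analytic_target_mask(scene, traj, fov, 1L),
           scene = scene)
    })
  })
}
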