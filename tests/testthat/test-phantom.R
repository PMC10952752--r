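test_that("signal_te follows mono-exponential decay", {
  expect_equal(signal_te(100, 50, 0), 100)
  expect_equal(signal_te(100, 50, 50), 100 / exp(1))
  te <- seq(0, 300, by = 10)
  s <- signal_te(100, 60, te)
  expect_true(all(diff(s) < 0))  # monotone decreasing in TE
  expect_error(signal_te(100, -1, 50), class = "fetaltrack_argument_error")
})

test_that("sphere and fetal scenes have the advertised analytic structure", {
  sph <- make_sphere_world(radius_mm = 45)
  expect_equal(sph$components[[sph$target_index]]$center, c(0, 0, 0))
  expect_false(scene_membership(sph, c(0, 0, 45 + 1e-6)))
  expect_true(scene_membership(sph, c(0, 0, 44.9)))

  fet <- make_fetal_world(head_radii_mm = c(30, 25, 25),
                          head_center = c(5, -4, 2))
  expect_equal(fet$components[[fet$target_index]]$center, c(5, -4, 2))
  expect_error(make_sphere_world(radius_mm = -3),
               class = "fetaltrack_argument_error")
})

test_that("rasterized target volumes match the analytic ellipsoid volume", {
  cfg <- acquisition_config(edge = 64L, spacing_mm = 3)
  fov <- grid_geometry(rep(64L, 3), 3)
  traj <- step_trajectory(list(), 1L)

  sph <- make_sphere_world(radius_mm = 45)
  m <- analytic_target_mask(sph, traj, fov, 1L)
  vol_vox <- sum(m$values) * 3^3
  vol_true <- 4 / 3 * pi * 45^3
  # agreement within one voxel shell of the surface
  shell <- 4 * pi * 45^2 * 3
  expect_lt(abs(vol_vox - vol_true), shell)
  # CoM of the centered sphere sits at the FOV center within half a voxel
  expect_lt(max(abs(center_of_mass(m))), 1.5)

  fet <- make_fetal_world(head_radii_mm = c(30, 25, 20), confounder = NULL)
  mf <- analytic_target_mask(fet, traj, fov, 1L)
  vol_f <- 4 / 3 * pi * 30 * 25 * 20
  shell_f <- 4 * pi * 25^2 * 3 * 1.6
  expect_lt(abs(sum(mf$values) * 27 - vol_f), shell_f)
})

test_that("a confounder of equal intensity yields two components under thresholding", {
  fet <- make_fetal_world(
    head_radii_mm = c(30, 25, 25),
    confounder = scene_component("sphere", c(65, 0, 0), 13,
                                 s0 = 100, t2star_ms = 60),
    background_s0 = 0
  )
  cfg <- acquisition_config(edge = 64L, noise_sigma = 0)
  traj <- step_trajectory(list(), 1L)
  vol <- acquire_repetition(fet, traj, acq_geometry(cfg), 1L, 90, cfg)
  fg <- vol$values > max(vol$values) / 2
  lab <- fetaltrack:::cpp_label3d(fg, as.integer(dim(fg)))
  expect_identical(max(lab), 2L)
})

test_that("step trajectories accumulate events piecewise-constantly", {
  tr0 <- step_trajectory(list(), 5)
  expect_true(all(tr0$offsets == 0))

  tr <- step_trajectory(list(motion_event(7, c(9, 0, 0))), 12)
  expect_equal(unname(tr$offsets[1:6, 1]), rep(0, 6))
  expect_equal(unname(tr$offsets[7:12, 1]), rep(9, 6))

  # stacked events on one axis sum cumulatively, independent of list order
  ev <- list(motion_event(3, c(2, 0, 0)), motion_event(8, c(5, 0, 0)))
  tr2a <- step_trajectory(ev, 10)
  tr2b <- step_trajectory(rev(ev), 10)
  expect_identical(tr2a$offsets, tr2b$offsets)
  expect_equal(unname(tr2a$offsets[10, ]), c(7, 0, 0))
  expect_equal(unname(tr2a$offsets[5, ]), c(2, 0, 0))

  expect_error(step_trajectory(list(motion_event(11, c(1, 0, 0))), 10),
               class = "fetaltrack_argument_error")
})

test_that("acquisition is deterministic and static scenes repeat exactly", {
  scene <- make_sphere_world(45)
  cfg <- acquisition_config(edge = 32L, spacing_mm = 6, noise_sigma = 2,
                            seed = 7L, n_repetitions = 3L)
  traj <- step_trajectory(list(), 3L)
  fov <- acq_geometry(cfg)
  a <- acquire_repetition(scene, traj, fov, 1L, 90, cfg)
  b <- acquire_repetition(scene, traj, fov, 1L, 90, cfg)
  expect_identical(a$values, b$values)  # same seed, same repetition
  # different repetitions draw independent noise
  c2 <- acquire_repetition(scene, traj, fov, 2L, 90, cfg)
  expect_false(identical(a$values, c2$values))

  cfg0 <- acquisition_config(edge = 32L, spacing_mm = 6, noise_sigma = 0,
                             n_repetitions = 2L)
  a0 <- acquire_repetition(scene, step_trajectory(list(), 2L), fov, 1L, 90, cfg0)
  b0 <- acquire_repetition(scene, step_trajectory(list(), 2L), fov, 2L, 90, cfg0)
  expect_identical(a0$values, b0$values)  # noise-free static scene
})

test_that("translating target and FOV together leaves the image unchanged", {
  scene <- make_sphere_world(40)
  cfg <- acquisition_config(edge = 32L, spacing_mm = 6, noise_sigma = 0)
  delta <- c(9, -6, 3)
  traj0 <- step_trajectory(list(), 1L)
  trajd <- step_trajectory(list(motion_event(1, delta)), 1L)
  ref <- acquire_repetition(scene, traj0, acq_geometry(cfg), 1L, 90, cfg)
  shifted <- acquire_repetition(scene, trajd, acq_geometry(cfg, delta), 1L, 90, cfg)
  expect_identical(ref$values, shifted$values)
})

test_that("multi-echo signals decay consistently inside one component", {
  scene <- make_sphere_world(40, s0 = 80, t2star_ms = 55)
  cfg <- acquisition_config(edge = 16L, spacing_mm = 12, noise_sigma = 0,
                            te_ms = c(30, 90, 150))
  traj <- step_trajectory(list(), 1L)
  fov <- acq_geometry(cfg)
  vols <- lapply(cfg$te_ms, function(te) {
    acquire_repetition(scene, traj, fov, 1L, te, cfg)
  })
  inside <- analytic_target_mask(scene, traj, fov, 1L)$values
  for (i in seq_along(cfg$te_ms)) {
    expect_equal(unique(vols[[i]]$values[inside]),
                 signal_te(80, 55, cfg$te_ms[i]))
  }
})

test_that("analytic masks re-rasterize stably under integer-voxel FOV shifts", {
  scene <- make_sphere_world(40)
  cfg <- acquisition_config(edge = 32L, spacing_mm = 6)
  traj <- step_trajectory(list(), 1L)
  m0 <- analytic_target_mask(scene, traj, acq_geometry(cfg), 1L)
  m1 <- analytic_target_mask(scene, traj, acq_geometry(cfg, c(6, -12, 18)), 1L)
  expect_identical(sum(m0$values), sum(m1$values))
  # target fully outside the FOV gives an empty mask
  far <- acq_geometry(cfg, c(1000, 0, 0))
  expect_identical(sum(analytic_target_mask(scene, traj, far, 1L)$values), 0L)
})

test_that("simulate_series writes a 4D NIfTI plus a trajectory CSV", {
  scene <- make_sphere_world(40)
  cfg <- acquisition_config(edge = 16L, spacing_mm = 12, n_repetitions = 4L)
  traj <- step_trajectory(list(motion_event(3, c(12, 0, 0))), 4L)
  nii <- tempfile(fileext = ".nii.gz")
  csv <- tempfile(fileext = ".csv")
  simulate_series(scene, traj, cfg, nii, csv)
  back <- load_volume(nii)
  expect_length(back, 4)
  tr <- read.csv(csv)
  expect_identical(names(tr), c("repetition", "dx_mm", "dy_mm", "dz_mm"))
  expect_equal(tr$dx_mm, c(0, 0, 12, 12))
})
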