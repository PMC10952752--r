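test_that("center_of_mass averages voxel indices in world coordinates", {
  g <- grid_geometry(c(3, 3, 3), 1, c(0, 0, 0))
  v <- array(FALSE, c(3, 3, 3))
  v[1, 1, 1] <- TRUE
  v[3, 1, 1] <- TRUE
  com <- center_of_mass(binary_mask(v, g))
  expect_equal(unname(com), c(0, -1, -1))

  empty <- binary_mask(array(FALSE, c(3, 3, 3)), g)
  out <- center_of_mass(empty)
  expect_true(all(is.na(out)))
  expect_true(attr(out, "empty"))
})

test_that("displacement estimation differences CoM at n and n-2", {
  rec <- tibble::tibble(repetition = 1:4,
                        com_x = c(0, 1, 9, NA), com_y = c(0, 0, 0, 0),
                        com_z = c(0, 0, 0, 0))
  expect_null(estimate_displacement(rec, 2))  # warm-up
  d <- estimate_displacement(rec, 3)
  expect_equal(as.numeric(d), c(9, 0, 0))
  expect_identical(attr(d, "from"), 1L)
  expect_identical(attr(d, "to"), 3L)
  expect_null(estimate_displacement(rec, 4))  # NA at n
  rec$com_x[1] <- NA
  expect_null(estimate_displacement(rec, 3))  # NA at n-2
})

test_that("the recentering correction is pending-aware and clipped", {
  rec <- tibble::tibble(repetition = 1L, com_x = 9, com_y = 0, com_z = 0)
  fs <- new_fov_state(c(0, 0, 0))
  adv <- fetaltrack:::fov_advance(fs, 1L)
  fs <- adv$fs
  expect_equal(compute_correction(rec, fs, 1L), c(9, 0, 0))
  # a queued shift of the same size cancels the correction (no double fire)
  fs2 <- apply_fov_update(fs, c(9, 0, 0), computed_at = 1L, latency = 2L)
  expect_equal(compute_correction(rec, fs2, 1L), c(0, 0, 0))
  # per-axis clipping
  expect_equal(compute_correction(rec, fs, 1L, max_shift_mm = 5), c(5, 0, 0))
  # centered object, nothing pending -> zero
  rec0 <- tibble::tibble(repetition = 1L, com_x = 0, com_y = 0, com_z = 0)
  expect_equal(compute_correction(rec0, fs, 1L), c(0, 0, 0))
})

test_that("queued FOV updates take effect exactly latency repetitions later", {
  fs <- new_fov_state(c(0, 0, 0))
  # reps 1..7 static, correction computed from rep 7's image
  for (n in 1:7) {
    adv <- fetaltrack:::fov_advance(fs, n)
    fs <- adv$fs
  }
  fs <- apply_fov_update(fs, c(9, 0, 0), computed_at = 7L, latency = 2L)
  centers <- numeric(0)
  for (n in 8:10) {
    adv <- fetaltrack:::fov_advance(fs, n)
    fs <- adv$fs
    centers <- c(centers, adv$center[1])
  }
  expect_equal(centers, c(0, 9, 9))  # center changes at repetition 9

  # zero corrections leave the state untouched
  fs0 <- new_fov_state(c(1, 2, 3))
  expect_identical(apply_fov_update(fs0, c(0, 0, 0), 1L, 2L), fs0)

  # two corrections queued for the same repetition sum
  fs2 <- new_fov_state(c(0, 0, 0))
  adv <- fetaltrack:::fov_advance(fs2, 1L)
  fs2 <- adv$fs
  fs2 <- apply_fov_update(fs2, c(1, 0, 0), 1L, 2L)
  fs2 <- apply_fov_update(fs2, c(0, 2, 0), 1L, 2L)
  adv <- fetaltrack:::fov_advance(fs2, 2L)
  fs2 <- adv$fs
  adv <- fetaltrack:::fov_advance(fs2, 3L)
  expect_equal(adv$center, c(1, 2, 0))
})

test_that("a static object produces no shifts and a constant FOV", {
  cfg <- default_sphere_cfg(n_repetitions = 10L, events = list())
  run <- run_closed_loop(cfg$scene, cfg$trajectory, cfg$acq, cfg$loop)
  expect_identical(nrow(run), 10L)
  expect_true(all(run$shift_x == 0 & run$shift_y == 0 & run$shift_z == 0))
  expect_true(all(run$fov_x == 0 & run$fov_y == 0 & run$fov_z == 0))
  expect_false(any(run$empty_flag))
})

test_that("the latency law holds for configurable latencies", {
  for (lat in c(1L, 2L, 3L)) {
    cfg <- phantom_config(n_repetitions = 14L, edge = 32L, radius_mm = 30,
                          events = list(motion_event(6, c(6, 0, 0))),
                          latency_repetitions = lat)
    run <- run_closed_loop(cfg$scene, cfg$trajectory, cfg$acq, cfg$loop)
    shift_rep <- run$repetition[abs(run$shift_x) > 0]
    expect_identical(shift_rep, 6L + lat)
    # exactly one shift per event, no oscillation
    expect_identical(sum(abs(run$shift_x) + abs(run$shift_y) +
                           abs(run$shift_z) > 0), 1L)
    # after the correction the image-frame CoM offset is sub-voxel
    spacing <- cfg$acq$spacing_mm
    post <- run[run$repetition > 6L + lat, ]
    expect_lt(max(abs(c(post$resid_x, post$resid_y, post$resid_z))),
              0.5 * spacing)
  }
})

test_that("world-frame CoM of a static object is invariant under FOV shifts", {
  scene <- make_sphere_world(40)
  cfg <- acquisition_config(edge = 32L, spacing_mm = 6, noise_sigma = 0)
  traj <- step_trajectory(list(), 1L)
  coms <- sapply(list(c(0, 0, 0), c(6, -12, 18), c(-24, 6, 0)), function(fc) {
    vol <- acquire_repetition(scene, traj, acq_geometry(cfg, fc), 1L, 90, cfg)
    center_of_mass(segment_intensity(vol))
  })
  spread <- apply(coms, 1, function(r) diff(range(r)))
  expect_lt(max(spread), 0.5 * 6)  # within half a voxel
})

test_that("localizer failures are flagged and the loop holds the FOV", {
  cfg <- default_sphere_cfg(n_repetitions = 8L,
                            events = list(motion_event(4, c(6, 0, 0))))
  flaky <- function(volume) {
    if (volume$repetition %in% c(4L, 5L)) stop("localizer glitch")
    segment_intensity(volume)
  }
  run <- run_closed_loop(cfg$scene, cfg$trajectory, cfg$acq, cfg$loop,
                         localizer = flaky)
  expect_identical(nrow(run), 8L)
  expect_true(all(run$empty_flag[4:5]))
  expect_true(all(is.na(run$com_x[4:5])))
  # no update was queued while the localizer was down
  expect_true(all(run$shift_x[1:6] == 0))
  # once it recovers (rep 6) the correction lands at rep 6 + latency
  expect_identical(run$repetition[run$shift_x != 0], 8L)
})

test_that("implausible mask volumes suppress corrections", {
  cfg <- default_sphere_cfg(n_repetitions = 6L,
                            events = list(motion_event(3, c(6, 0, 0))))
  # bounds exclude the sphere volume (~382 ml)
  loop <- loop_config(min_volume_ml = 1, max_volume_ml = 10)
  run <- run_closed_loop(cfg$scene, cfg$trajectory, cfg$acq, loop)
  expect_true(all(run$implausible_flag))
  expect_true(all(run$shift_x == 0))
  expect_true(all(run$fov_x == 0))
})

test_that("audit trails round-trip through CSV", {
  cfg <- default_sphere_cfg(n_repetitions = 6L,
                            events = list(motion_event(3, c(6, 0, 0))))
  run <- run_closed_loop(cfg$scene, cfg$trajectory, cfg$acq, cfg$loop)
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_audit_trail(run, csv, json)
  back <- read.csv(csv)
  expect_identical(nrow(back), 6L)
  expect_true(all(c("repetition", "fov_x", "com_x", "disp_x", "shift_x",
                    "empty_flag") %in% names(back)))
  expect_true(file.exists(json))
  g <- glance(run)
  expect_identical(g$n_repetitions, 6L)
})
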