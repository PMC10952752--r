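test_that("dice and iou match hand counts and handle empty masks", {
  g <- geom_iso(2)
  a <- array(FALSE, c(2, 2, 2))
  b <- array(FALSE, c(2, 2, 2))
  a[1:2, 1, 1] <- TRUE               # |A| = 2
  b[1:2, 1:2, 1] <- TRUE             # |B| = 4, overlap 2
  expect_equal(dice(binary_mask(a, g), binary_mask(b, g)), 2 / 3)
  expect_equal(iou(binary_mask(a, g), binary_mask(b, g)), 0.5)

  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)
  disj <- array(FALSE, c(2, 2, 2))
  disj[1, 2, 2] <- TRUE
  expect_equal(dice(a, disj), 0)
  expect_equal(iou(a, disj), 0)

  none <- array(FALSE, c(2, 2, 2))
  expect_equal(dice(none, none), 1)  # both empty: perfect agreement
  expect_equal(iou(none, none), 1)
  expect_equal(dice(a, none), 0)     # one empty

  g2 <- geom_iso(2, 1, center = c(5, 0, 0))
  expect_error(dice(binary_mask(a, g), binary_mask(a, g2)),
               class = "fetaltrack_argument_error")
  expect_error(iou(a, array(FALSE, c(3, 3, 3))),
               class = "fetaltrack_argument_error")
})

test_that("IoU = DSC / (2 - DSC) and both metrics are symmetric", {
  set.seed(61)
  g <- geom_iso(4)
  for (i in 1:500) {
    a <- random_mask(g, runif(1, 0.05, 0.6))
    b <- random_mask(g, runif(1, 0.05, 0.6))
    d <- dice(a, b)
    j <- iou(a, b)
    expect_equal(j, d / (2 - d))
    expect_identical(d, dice(b, a))
    expect_identical(j, iou(b, a))
    expect_lte(j, d)
  }
})

test_that("growing the overlap never decreases DSC or IoU", {
  g <- geom_iso(4)
  n <- 64
  # |A| = |B| = 16 with overlap k = 0..16
  for (k in c(0, 4, 8, 12, 16)) {
    av <- rep(FALSE, n)
    bv <- rep(FALSE, n)
    av[1:16] <- TRUE
    bv[(17 - k):(32 - k)] <- TRUE
    d <- dice(array(av, c(4, 4, 4)), array(bv, c(4, 4, 4)))
    j <- iou(array(av, c(4, 4, 4)), array(bv, c(4, 4, 4)))
    expect_equal(d, 2 * k / 32)
    expect_equal(j, ifelse(k == 0, 0, k / (32 - k)))
  }
})

test_that("com_mse computes per-axis means of squared differences", {
  p <- matrix(0, 10, 3)
  expect_equal(com_mse(p, p)$mse, c(0, 0, 0))

  t <- p
  p2 <- p
  p2[, 1] <- p2[, 1] + 1  # constant +1 mm offset in x
  r <- com_mse(p2, t)
  expect_equal(r$mse, c(1, 0, 0))
  expect_equal(r$rmse, c(1, 0, 0))
  expect_equal(r$mse_sd, c(0, 0, 0))

  single <- com_mse(matrix(c(1, 2, 3), 1), matrix(c(0, 0, 0), 1))
  expect_equal(single$mse, c(1, 4, 9))
  expect_equal(single$mse_sd, c(0, 0, 0))  # degenerate n = 1

  withNA <- rbind(c(NA, 0, 0), c(2, 0, 0))
  r2 <- com_mse(withNA, matrix(0, 2, 3))
  expect_identical(unique(r2$n), 1L)
  expect_equal(r2$mse, c(4, 0, 0))

  expect_error(com_mse(matrix(0, 2, 3), matrix(0, 3, 3)),
               class = "fetaltrack_argument_error")
})

test_that("grouped summaries equal brute-force recomputation", {
  rec <- tibble::tibble(
    id = 1:6,
    te_index = c(1, 1, 2, 2, 2, 1),
    ga_class = c("<=23", ">23", "<=23", ">23", ">23", ">23"),
    dsc = c(0.8, 0.9, 0.7, 0.95, 0.85, 0.88),
    iou = c(0.67, 0.82, 0.54, 0.90, 0.74, 0.79)
  )
  s <- summarize_groups(rec, by = "te_index")
  expect_identical(nrow(s), 2L)
  for (te in c(1, 2)) {
    sub <- rec[rec$te_index == te, ]
    row <- s[s$te_index == te, ]
    expect_equal(row$dsc_mean, mean(sub$dsc), tolerance = 1e-12)
    expect_equal(row$dsc_sd, sd(sub$dsc), tolerance = 1e-12)
    expect_equal(row$iou_mean, mean(sub$iou), tolerance = 1e-12)
  }
  # one record per group: mean = value, sd = 0
  s1 <- summarize_groups(rec[1:2, ], by = c("te_index", "ga_class"))
  expect_true(all(s1$dsc_sd == 0))
  expect_equal(sort(s1$dsc_mean), sort(rec$dsc[1:2]))
  # unused factor level warns and is omitted
  rec$position <- factor(rep("cephalic", 6), levels = c("cephalic", "breech"))
  expect_warning(s2 <- summarize_groups(rec, by = "position"), "breech")
  expect_identical(nrow(s2), 1L)
  expect_error(summarize_groups(rec, by = "nope"),
               class = "fetaltrack_argument_error")
})

test_that("the phantom experiment reproduces recentering with exact latency", {
  cfg <- phantom_config(n_repetitions = 24L, edge = 32L, radius_mm = 30,
                        events = list(motion_event(7, c(9, 0, 0)),
                                      motion_event(18, c(0, -6, 0))))
  rep <- run_phantom_experiment(cfg)
  expect_identical(rep$latency$correction_rep, c(9L, 20L))
  expect_identical(rep$latency$latency, c(2L, 2L))
  expect_true(all(rep$passes))
  expect_lt(max(abs(c(rep$residuals$dvox_x, rep$residuals$dvox_y,
                      rep$residuals$dvox_z))), 1)
})

test_that("latency config passes through to the report", {
  cfg <- phantom_config(n_repetitions = 16L, edge = 32L, radius_mm = 30,
                        events = list(motion_event(6, c(6, 0, 0))),
                        latency_repetitions = 3L)
  rep <- run_phantom_experiment(cfg)
  expect_identical(rep$latency$latency, 3L)
})

test_that("an untrained network localizer still yields a complete flagged report", {
  model <- build_localizer_network(network_spec("tiny", input_edge = 32L),
                                   seed = 77)
  cfg <- phantom_config(n_repetitions = 6L, edge = 32L, radius_mm = 30,
                        events = list(motion_event(3, c(6, 0, 0))),
                        localizer = model)
  # plausibility band sized to the actual phantom volume (~113 ml)
  cfg$loop <- loop_config(localizer = model, min_volume_ml = 80,
                          max_volume_ml = 150)
  rep <- run_phantom_experiment(cfg)
  expect_identical(nrow(rep$records), 6L)
  expect_true(rep$passes["loop_completed"])
  # untrained output is noise: flagged as empty or implausible somewhere
  expect_gt(sum(rep$records$empty_flag | rep$records$implausible_flag), 0)
})

test_that("autoplot methods return ggplot objects", {
  cfg <- default_sphere_cfg(n_repetitions = 6L,
                            events = list(motion_event(3, c(6, 0, 0))))
  run <- run_closed_loop(cfg$scene, cfg$trajectory, cfg$acq, cfg$loop)
  expect_s3_class(autoplot(run), "ggplot")
  rep <- run_phantom_experiment(default_sphere_cfg(n_repetitions = 10L))
  expect_s3_class(autoplot(rep), "ggplot")
})
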