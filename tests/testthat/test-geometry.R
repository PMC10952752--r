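test_that("voxel/world mappings are exact inverses with the midpoint at the FOV center", {
  g <- grid_geometry(c(128, 128, 128), 3, c(0, 0, 0))
  # continuous midpoint maps to the FOV center
  expect_equal(voxel_to_world((g$shape + 1) / 2, g), c(0, 0, 0))
  expect_equal(world_to_voxel(c(0, 0, 0), g), (g$shape + 1) / 2)
  # one spacing to the +x of center
  expect_equal(voxel_to_world(c(65.5, 64.5, 64.5), g), c(3, 0, 0))
  expect_equal(world_to_voxel(c(3, 0, 0), g), c(65.5, 64.5, 64.5))

  # anisotropic, offset geometry round-trips for 1000 random points
  set.seed(11)
  g2 <- grid_geometry(c(31, 64, 17), c(1.5, 2, 3.25), c(-10, 4, 7))
  pts <- matrix(runif(3000, -200, 200), ncol = 3)
  back <- voxel_to_world(world_to_voxel(pts, g2), g2)
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("invalid geometries are rejected", {
  expect_error(grid_geometry(c(0, 4, 4), 1), class = "fetaltrack_argument_error")
  expect_error(grid_geometry(c(4, 4, 4), c(1, -1, 1)),
               class = "fetaltrack_argument_error")
  expect_error(grid_geometry(c(4, 4, 4), 1, c(NA, 0, 0)),
               class = "fetaltrack_argument_error")
})

test_that("pad_crop_to_grid pads small inputs centrally and crops large ones", {
  set.seed(3)
  v100 <- volume_grid(array(runif(100^3), rep(100, 3)), geom_iso(100, 3))
  out <- pad_crop_to_grid(v100, 128)
  expect_identical(dim(out$values), rep(128L, 3))
  expect_identical(out$values[15:114, 15:114, 15:114], v100$values)
  expect_equal(sum(out$values), sum(v100$values))  # padding conserves intensity

  # 128^3 input passes through unchanged
  v128 <- volume_grid(array(runif(16^3), rep(16, 3)), geom_iso(16, 3))
  expect_identical(pad_crop_to_grid(v128, 16)$values, v128$values)

  # cropping keeps the central block, against direct index arithmetic
  v150 <- volume_grid(array(as.numeric(seq_len(20^3)), rep(20, 3)),
                      geom_iso(20, 3))
  out <- pad_crop_to_grid(v150, 16)
  expect_identical(out$values, v150$values[3:18, 3:18, 3:18])

  expect_error(pad_crop_to_grid(v128, 0), class = "fetaltrack_argument_error")
})

test_that("pad_crop_to_grid preserves world coordinates and is idempotent", {
  set.seed(4)
  for (edge in c(10L, 15L, 20L)) {
    v <- volume_grid(array(runif(edge^3), rep(edge, 3)),
                     geom_iso(edge, 2, center = c(5, -3, 1)))
    out <- pad_crop_to_grid(v, 16)
    # a voxel kept in both grids has the same world coordinate
    src <- if (edge <= 16) c(1, 1, 1) else rep((edge - 16) %/% 2 + 1, 3)
    dst <- if (edge <= 16) rep((16 - edge) %/% 2 + 1, 3) else c(1, 1, 1)
    expect_equal(voxel_to_world(dst, out$geometry),
                 voxel_to_world(src, v$geometry))
    twice <- pad_crop_to_grid(out, 16)
    expect_identical(twice$values, out$values)
    expect_equal(twice$geometry$fov_center, out$geometry$fov_center)
  }
})

test_that("masks pad/crop as masks and anisotropic volumes are resampled first", {
  m <- binary_mask(array(TRUE, c(6, 6, 6)), geom_iso(6, 2))
  out <- pad_crop_to_grid(m, 8)
  expect_s3_class(out, "binary_mask")
  expect_identical(sum(out$values), sum(m$values))

  va <- volume_grid(array(1, c(8, 8, 4)), grid_geometry(c(8, 8, 4), c(1, 1, 2)))
  out <- pad_crop_to_grid(va, 16)
  expect_identical(dim(out$values), rep(16L, 3))
  expect_equal(out$geometry$spacing, rep(1, 3))
  # interior of the resampled slab keeps the constant intensity
  expect_equal(out$values[8, 8, 8], 1)
})
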