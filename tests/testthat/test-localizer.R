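test_that("generalized Dice loss matches hand-worked and perfect cases", {
  g <- geom_iso(2)
  # perfect one-hot prediction, both classes present -> 0
  onehot <- array(0, c(2, 2, 2, 2))
  onehot[, , , 1] <- 1
  onehot[1, 1, 1, ] <- c(0, 1)
  onehot[2, 1, 1, ] <- c(0, 1)
  expect_equal(generalized_dice_loss(onehot, onehot), 0)

  # 8 voxels, 2 foreground, all-background prediction -> 0.625
  allbg <- array(0, c(2, 2, 2, 2))
  allbg[, , , 1] <- 1
  expect_equal(generalized_dice_loss(allbg, onehot), 0.625)

  # invariant under voxel permutation
  set.seed(31)
  pair <- random_gdl_pair(3)
  perm <- sample(27)
  pm <- matrix(pair$probs, ncol = 2)[perm, ]
  tm <- matrix(pair$onehot, ncol = 2)[perm, ]
  expect_equal(
    generalized_dice_loss(array(pm, c(3, 3, 3, 2)), array(tm, c(3, 3, 3, 2))),
    generalized_dice_loss(pair$probs, pair$onehot)
  )

  expect_error(
    generalized_dice_loss(array(0.5, c(2, 2, 2, 2)), array(1, c(3, 3, 3, 2))),
    class = "fetaltrack_argument_error"
  )
})

test_that("generalized Dice loss equals an independent brute-force double loop", {
  set.seed(32)
  for (i in 1:200) {
    pair <- random_gdl_pair(sample(2:6, 1))
    fast <- generalized_dice_loss(pair$probs, pair$onehot)
    slow <- gdl_brute(pair$probs, pair$onehot)
    expect_lt(abs(fast - slow), 1e-10)
    expect_gte(fast, 0)
    expect_lte(fast, 1)
  }
})

test_that("probability and label maps enforce their invariants", {
  g <- geom_iso(2)
  bad <- array(0.4, c(2, 2, 2, 2))  # sums to 0.8
  expect_error(probability_map(bad, g), class = "fetaltrack_argument_error")
  ok <- array(0.5, c(2, 2, 2, 2))
  expect_s3_class(probability_map(ok, g), "probability_map")
  twoones <- array(1, c(2, 2, 2, 2))
  expect_error(label_map(twoones, g), class = "fetaltrack_argument_error")
  m <- random_mask(g)
  lm <- mask_to_label_map(m)
  expect_s3_class(lm, "label_map")
  expect_equal(lm$onehot[, , , 2] == 1, unname(m$values), ignore_attr = TRUE)
})

test_that("the default network spec matches the deployed architecture", {
  sp <- network_spec()
  expect_identical(sp$levels, 5L)
  expect_identical(sp$channels, c(32L, 64L, 128L, 256L, 512L))
  expect_identical(sp$pooling, c("avg", "avg", "max", "max"))
  expect_identical(sp$normalization, "instance")
  expect_identical(sp$activation, "leaky_relu")
  expect_identical(sp$out_channels, 2L)
  expect_identical(sp$blocks_per_stage, 2L)
  expect_identical(sp$kernel, c(3L, 3L, 3L))
  expect_identical(sp$stride, 1L)

  expect_error(network_spec(channels = c(8, 16, 32)),
               class = "fetaltrack_config_error")
  expect_error(network_spec(channels = c(32, 16, 64, 128, 256)),
               class = "fetaltrack_config_error")
  expect_error(network_spec(input_edge = 100),  # not divisible by 16
               class = "fetaltrack_config_error")
})

test_that("the instantiated network maps e^3 inputs to e^3 x 2 outputs", {
  model <- build_localizer_network(network_spec("tiny", input_edge = 32L),
                                   seed = 5)
  x <- array(runif(32^3), rep(32, 3))
  fw <- fetaltrack:::unet_forward(model, x)
  expect_identical(dim(fw$probs), c(32L, 32L, 32L, 2L))
  sums <- fw$probs[, , , 1] + fw$probs[, , , 2]
  expect_lt(max(abs(sums - 1)), 1e-6)
  # parameter shapes follow the channel plan
  expect_identical(dim(model$params$enc1_conv1_W), c(3L, 3L, 3L, 1L, 4L))
  expect_identical(dim(model$params$enc5_conv2_W), c(3L, 3L, 3L, 64L, 64L))
  expect_identical(dim(model$params$dec1_conv1_W), c(3L, 3L, 3L, 8L, 4L))
  expect_error(fetaltrack:::unet_forward(model, array(0, rep(16, 3))),
               class = "fetaltrack_argument_error")
})

test_that("predict_mask binarizes by argmax with ties to background", {
  g <- geom_iso(16, 3)
  model <- build_localizer_network(network_spec("tiny", input_edge = 16L),
                                   seed = 6)
  vol <- volume_grid(array(runif(16^3), rep(16, 3)), g)
  out <- predict_mask(model, vol)
  expect_s3_class(out$mask, "binary_mask")
  expect_s3_class(out$prob, "probability_map")
  # mask is exactly the strict-majority foreground voxels
  expect_equal(unname(out$mask$values),
               unname(out$prob$probs[, , , 2] > out$prob$probs[, , , 1]))
  # foreground and background partition the voxels
  expect_true(all(xor(out$mask$values,
                      out$prob$probs[, , , 1] >= out$prob$probs[, , , 2])))
  wrong <- volume_grid(array(0, rep(8, 3)), geom_iso(8, 3))
  expect_error(predict_mask(model, wrong), class = "fetaltrack_argument_error")
})

test_that("network weight init and training are reproducible for a fixed seed", {
  a <- build_localizer_network(network_spec("tiny", input_edge = 16L), seed = 9)
  b <- build_localizer_network(network_spec("tiny", input_edge = 16L), seed = 9)
  expect_identical(a$params, b$params)

  ds <- synth_head_dataset(3, edge = 16, spacing_mm = 12, seed = 41)
  cfg <- train_config(epochs = 1, seed = 3)
  spec <- network_spec("tiny", input_edge = 16L)
  f1 <- train_localizer(ds[1:2], ds[3], cfg,
                        model = build_localizer_network(spec, seed = 3))
  f2 <- train_localizer(ds[1:2], ds[3], cfg,
                        model = build_localizer_network(spec, seed = 3))
  expect_identical(f1$history, f2$history)
})

test_that("one epoch of training decreases the generalized Dice loss", {
  ds <- synth_head_dataset(4, edge = 32, spacing_mm = 6, seed = 42)
  spec <- network_spec("tiny", input_edge = 32L)
  model <- build_localizer_network(spec, seed = 1)
  # loss of the untrained model
  gdl_of <- function(m) {
    mean(vapply(ds, function(s) {
      fw <- fetaltrack:::unet_forward(m, normalize_volume(s$volume$values))
      generalized_dice_loss(fw$probs,
                            mask_to_label_map(s$mask)$onehot)
    }, numeric(1)))
  }
  before <- gdl_of(model)
  fit <- train_localizer(ds, list(), train_config(epochs = 1, seed = 1),
                         model = model)
  after <- gdl_of(fit$model)
  expect_lt(after, before)
  expect_identical(nrow(fit$history), 1L)
  expect_error(train_localizer(list(), list(), train_config()),
               class = "fetaltrack_argument_error")
})

test_that("checkpoints round-trip the model", {
  model <- build_localizer_network(network_spec("tiny", input_edge = 16L),
                                   seed = 2)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_error(load_checkpoint(tempfile()), class = "fetaltrack_io_error")
})
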