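#' 3D UNet architecture specification
#'
#' The localization network is a five-level 3D UNet: each encoder stage has
#' two repeated blocks of 3x3x3 convolution (stride 1), instance
#' normalization and LeakyReLU; the first two downsamplings are 2x2x2
#' average pooling, the remaining two 2x2x2 max pooling. The decoder
#' mirrors the encoder with trilinear upsampling followed by convolution
#' and channel-concatenation skip connections, and ends in a 1x1x1
#' convolution to `out_channels = 2` classes (background, brain/target).
#'
#' The default (`profile = "full"`) uses channels (32, 64, 128, 256, 512)
#' on a 128^3 input, the configuration whose architecture fidelity the
#' tests introspect. `"small"` (16, 32, 64, 128, 256) and `"tiny"`
#' (4, 8, 16, 32, 64), both on a 64^3 input, keep the same architecture
#' family at CPU-friendly cost; `"tiny"` is the profile the shipped
#' training experiments use.
#'
#' @param profile one of `"full"`, `"small"`, `"tiny"`; or set `channels`
#'   and `input_edge` explicitly.
#' @param channels integer vector of 5 strictly increasing channel widths.
#' @param input_edge input grid edge; must be divisible by
#'   `2^(levels - 1) = 16`.
#' @param out_channels number of output classes (2: background, target).
#' @param leaky_slope negative slope of the LeakyReLU activations.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(profile = c("full", "small", "tiny"),
                         channels = NULL, input_edge = NULL,
                         out_channels = 2L, leaky_slope = 0.01) {
  profile <- match.arg(profile)
  defaults <- list(
    full  = list(channels = c(32L, 64L, 128L, 256L, 512L), input_edge = 128L),
    small = list(channels = c(16L, 32L, 64L, 128L, 256L), input_edge = 64L),
    tiny  = list(channels = c(4L, 8L, 16L, 32L, 64L), input_edge = 64L)
  )[[profile]]
  channels <- as.integer(channels %||% defaults$channels)
  input_edge <- as.integer(input_edge %||% defaults$input_edge)
  if (length(channels) != 5L) {
    abort("`channels` must list exactly 5 channel widths",
          class = "fetaltrack_config_error")
  }
  if (any(diff(channels) <= 0)) {
    abort("`channels` must be strictly increasing",
          class = "fetaltrack_config_error")
  }
  levels <- 5L
  if (input_edge %% 2^(levels - 1) != 0) {
    abort(sprintf("`input_edge` must be divisible by %d", 2^(levels - 1)),
          class = "fetaltrack_config_error")
  }
  structure(list(
    levels = levels, channels = channels, input_edge = input_edge,
    kernel = c(3L, 3L, 3L), stride = 1L, blocks_per_stage = 2L,
    normalization = "instance", activation = "leaky_relu",
    leaky_slope = leaky_slope,
    pooling = c("avg", "avg", "max", "max"), pool_size = c(2L, 2L, 2L),
    upsampling = "trilinear", skip = "concat",
    out_channels = as.integer(out_channels), profile = profile
  ), class = "network_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<network_spec> 3D UNet '%s': %d levels, channels (%s), input %d^3\n",
    "  2x [conv 3x3x3 + %s norm + LeakyReLU(%g)] per stage\n",
    "  pooling: %s (2x2x2); upsampling: %s; skips: %s; %d output classes\n"),
    x$profile, x$levels, paste(x$channels, collapse = ", "), x$input_edge,
    x$normalization, x$leaky_slope, paste(x$pooling, collapse = "/"),
    x$upsampling, x$skip, x$out_channels))
  invisible(x)
}

he_init <- function(shape, fan_in) {
  array(rnorm(prod(shape), 0, sqrt(2 / fan_in)), dim = shape)
}

#' Instantiate a trainable 3D UNet localizer
#'
#' Builds the network described by a [network_spec()] with He-initialized
#' weights. The model is a plain parameter container; [predict_mask()]
#' runs inference and [train_localizer()] fits it with the generalized
#' Dice loss and Adam.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the weight initialization.
#' @return An object of class `unet3d`.
#' @export
build_localizer_network <- function(spec = network_spec(), seed = 0L) {
  stopifnot(inherits(spec, "network_spec"))
  ch <- spec$channels
  params <- list()
  with_preserved_seed({
    set.seed(seed)
    cin <- 1L
    for (i in 1:5) {
      params[[sprintf("enc%d_conv1_W", i)]] <- he_init(c(3, 3, 3, cin, ch[i]), 27 * cin)
      params[[sprintf("enc%d_conv1_b", i)]] <- numeric(ch[i])
      params[[sprintf("enc%d_conv2_W", i)]] <- he_init(c(3, 3, 3, ch[i], ch[i]), 27 * ch[i])
      params[[sprintf("enc%d_conv2_b", i)]] <- numeric(ch[i])
      cin <- ch[i]
    }
    for (i in 4:1) {
      params[[sprintf("up%d_W", i)]] <- he_init(c(3, 3, 3, ch[i + 1], ch[i]), 27 * ch[i + 1])
      params[[sprintf("up%d_b", i)]] <- numeric(ch[i])
      params[[sprintf("dec%d_conv1_W", i)]] <- he_init(c(3, 3, 3, 2 * ch[i], ch[i]), 27 * 2 * ch[i])
      params[[sprintf("dec%d_conv1_b", i)]] <- numeric(ch[i])
      params[[sprintf("dec%d_conv2_W", i)]] <- he_init(c(3, 3, 3, ch[i], ch[i]), 27 * ch[i])
      params[[sprintf("dec%d_conv2_b", i)]] <- numeric(ch[i])
    }
    params[["out_W"]] <- matrix(rnorm(ch[1] * spec$out_channels, 0, sqrt(2 / ch[1])),
                                ch[1], spec$out_channels)
    params[["out_b"]] <- numeric(spec$out_channels)
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 trained_epochs = 0L),
            class = "unet3d")
}

#' @export
print.unet3d <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<unet3d> %s parameters, init seed %d, trained epochs %d\n",
              format(np, big.mark = ","), x$seed, x$trained_epochs))
  print(x$spec)
  invisible(x)
}

# --- layer primitives (R side; convolutions/pooling/upsampling in C++) ----

conv3 <- function(x, W, b) {
  d <- dim(x)
  Wm <- W
  dim(Wm) <- c(27 * d[4], dim(W)[5])
  cpp_conv3d_fw(x, as.integer(d), Wm, b)
}

conv3_bw <- function(x, W, dy) {
  d <- dim(x)
  Wm <- W
  dim(Wm) <- c(27 * d[4], dim(W)[5])
  r <- cpp_conv3d_bw(x, as.integer(d), Wm, dy)
  dim(r$dW) <- dim(W)
  r
}

instnorm_fw <- function(z, eps = 1e-5) {
  cpp_instnorm_fw(z, as.integer(dim(z)), eps)
}

instnorm_bw <- function(dy, y, s) {
  cpp_instnorm_bw(dy, y, as.integer(dim(y)), s)
}

lrelu_fw <- function(y, slope) cpp_lrelu_fw(y, slope)

lrelu_bw <- function(da, y, slope) cpp_lrelu_bw(da, y, slope)

# conv + instance norm + LeakyReLU; cache holds what backward needs
block_fw <- function(x, W, b, slope, keep_cache = FALSE) {
  z <- conv3(x, W, b)
  nrm <- instnorm_fw(z)
  a <- lrelu_fw(nrm$y, slope)
  list(out = a,
       cache = if (keep_cache) list(x = x, y = nrm$y, s = nrm$s))
}

block_bw <- function(da, cache, W, slope) {
  dy <- lrelu_bw(da, cache$y, slope)
  dz <- instnorm_bw(dy, cache$y, cache$s)
  conv3_bw(cache$x, W, dz)
}

concat4 <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  array(c(a, b), dim = c(da[1:3], da[4] + db[4]))
}

#' Forward pass of the UNet localizer
#'
#' @param model a [unet3d] from [build_localizer_network()].
#' @param x 3D numeric array with edge `model$spec$input_edge` (already
#'   normalized; see [predict_mask()] for the user-facing entry point).
#' @param keep_cache keep intermediate activations for backpropagation.
#' @return list with `probs` (4D array, softmax over `out_channels`) and,
#'   if requested, `cache`.
#' @keywords internal
unet_forward <- function(model, x, keep_cache = FALSE) {
  sp <- model$spec
  P <- model$params
  slope <- sp$leaky_slope
  d <- dim(x)
  if (length(d) != 3L || any(d != sp$input_edge)) {
    abort(sprintf("input must be a %d^3 array", sp$input_edge),
          class = "fetaltrack_argument_error")
  }
  dim(x) <- c(d, 1L)
  cache <- list()
  enc <- list()
  cur <- x
  for (i in 1:5) {
    b1 <- block_fw(cur, P[[sprintf("enc%d_conv1_W", i)]],
                   P[[sprintf("enc%d_conv1_b", i)]], slope, keep_cache)
    b2 <- block_fw(b1$out, P[[sprintf("enc%d_conv2_W", i)]],
                   P[[sprintf("enc%d_conv2_b", i)]], slope, keep_cache)
    cache[[sprintf("enc%d_1", i)]] <- b1$cache
    cache[[sprintf("enc%d_2", i)]] <- b2$cache
    enc[[i]] <- b2$out
    if (i < 5) {
      mode <- if (sp$pooling[i] == "max") 1L else 0L
      pl <- cpp_pool_fw(b2$out, as.integer(dim(b2$out)), mode)
      cache[[sprintf("pool%d", i)]] <-
        if (keep_cache) list(mode = mode, arg = pl$arg, dims_in = dim(b2$out))
      cur <- pl$y
    }
  }
  cur <- enc[[5]]
  for (i in 4:1) {
    up <- cpp_upsample_fw(cur, as.integer(dim(cur)))
    cache[[sprintf("updims%d", i)]] <- if (keep_cache) dim(cur)
    ub <- block_fw(up, P[[sprintf("up%d_W", i)]], P[[sprintf("up%d_b", i)]],
                   slope, keep_cache)
    cache[[sprintf("up%d", i)]] <- ub$cache
    cat_in <- concat4(enc[[i]], ub$out)
    d1b <- block_fw(cat_in, P[[sprintf("dec%d_conv1_W", i)]],
                    P[[sprintf("dec%d_conv1_b", i)]], slope, keep_cache)
    d2b <- block_fw(d1b$out, P[[sprintf("dec%d_conv2_W", i)]],
                    P[[sprintf("dec%d_conv2_b", i)]], slope, keep_cache)
    cache[[sprintf("dec%d_1", i)]] <- d1b$cache
    cache[[sprintf("dec%d_2", i)]] <- d2b$cache
    cur <- d2b$out
  }
  dd <- dim(cur)
  m <- matrix(cur, ncol = dd[4])
  logits <- sweep(m %*% P$out_W, 2, P$out_b, "+")
  # softmax over classes
  mx <- logits[, 1]
  for (j in seq_len(ncol(logits))[-1]) mx <- pmax(mx, logits[, j])
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  dim(probs) <- c(dd[1:3], sp$out_channels)
  if (keep_cache) cache$final_in <- m
  list(probs = probs,
       cache = if (keep_cache) cache,
       enc_channels = sp$channels)
}

# backward pass: dprobs is dL/dp in matrix layout (nvox x classes)
unet_backward <- function(model, fw, dprobs_mat) {
  sp <- model$spec
  P <- model$params
  slope <- sp$leaky_slope
  cache <- fw$cache
  probs_m <- matrix(fw$probs, ncol = sp$out_channels)
  # softmax backward
  dot <- rowSums(dprobs_mat * probs_m)
  dlogits <- probs_m * (dprobs_mat - dot)
  grads <- list()
  m <- cache$final_in
  grads$out_W <- crossprod(m, dlogits)
  grads$out_b <- colSums(dlogits)
  dcur <- dlogits %*% t(P$out_W)
  edge <- sp$input_edge
  dim(dcur) <- c(rep(edge, 3), sp$channels[1])
  denc <- vector("list", 5)  # gradients flowing into encoder outputs
  for (i in 1:4) {
    r2 <- block_bw(dcur, cache[[sprintf("dec%d_2", i)]],
                   P[[sprintf("dec%d_conv2_W", i)]], slope)
    grads[[sprintf("dec%d_conv2_W", i)]] <- r2$dW
    grads[[sprintf("dec%d_conv2_b", i)]] <- r2$db
    r1 <- block_bw(r2$dx, cache[[sprintf("dec%d_1", i)]],
                   P[[sprintf("dec%d_conv1_W", i)]], slope)
    grads[[sprintf("dec%d_conv1_W", i)]] <- r1$dW
    grads[[sprintf("dec%d_conv1_b", i)]] <- r1$db
    dcat <- r1$dx
    ci <- sp$channels[i]
    dd <- dim(dcat)
    denc[[i]] <- dcat[, , , seq_len(ci), drop = FALSE]
    dub <- dcat[, , , ci + seq_len(ci), drop = FALSE]
    ru <- block_bw(dub, cache[[sprintf("up%d", i)]],
                   P[[sprintf("up%d_W", i)]], slope)
    grads[[sprintf("up%d_W", i)]] <- ru$dW
    grads[[sprintf("up%d_b", i)]] <- ru$db
    dcur <- cpp_upsample_bw(ru$dx, as.integer(cache[[sprintf("updims%d", i)]]))
  }
  denc[[5]] <- dcur
  for (i in 5:1) {
    dout <- denc[[i]]
    if (i < 5) {
      pc <- cache[[sprintf("pool%d", i)]]
      dpool <- cpp_pool_bw(dnext, as.integer(pc$dims_in), pc$mode, pc$arg)
      dout <- dout + dpool
    }
    r2 <- block_bw(dout, cache[[sprintf("enc%d_2", i)]],
                   P[[sprintf("enc%d_conv2_W", i)]], slope)
    grads[[sprintf("enc%d_conv2_W", i)]] <- r2$dW
    grads[[sprintf("enc%d_conv2_b", i)]] <- r2$db
    r1 <- block_bw(r2$dx, cache[[sprintf("enc%d_1", i)]],
                   P[[sprintf("enc%d_conv1_W", i)]], slope)
    grads[[sprintf("enc%d_conv1_W", i)]] <- r1$dW
    grads[[sprintf("enc%d_conv1_b", i)]] <- r1$db
    dnext <- r1$dx  # gradient into pooled input of stage i (from stage below)
  }
  grads
}

#' Segment a volume with the UNet localizer
#'
#' Normalizes the volume (per-volume 99th-percentile scaling to \[0, 1\]),
#' runs the forward pass, and binarizes the two-channel softmax output by
#' per-voxel argmax; exact ties go to background. An all-background result
#' is flagged (`attr(mask, "empty_flag")`), not an error — the tracking
#' loop treats it as a missing observation.
#'
#' @param model a [unet3d].
#' @param volume a [volume_grid()] whose grid edge equals the network input
#'   edge (use [pad_crop_to_grid()] first if needed).
#' @return list with `mask` (a [binary_mask()] with `empty_flag` attribute)
#'   and `prob` (a [probability_map()]).
#' @export
predict_mask <- function(model, volume) {
  stopifnot(inherits(model, "unet3d"), inherits(volume, "volume_grid"))
  d <- dim(volume$values)
  if (any(d != model$spec$input_edge)) {
    abort(sprintf("volume grid %s does not match network input edge %d",
                  paste(d, collapse = "x"), model$spec$input_edge),
          class = "fetaltrack_argument_error")
  }
  x <- normalize_volume(volume$values)
  fw <- unet_forward(model, x, keep_cache = FALSE)
  prob <- probability_map(fw$probs, volume$geometry)
  fg <- fw$probs[, , , 2] > fw$probs[, , , 1]  # tie -> background
  mask <- binary_mask(fg, volume$geometry)
  attr(mask, "empty_flag") <- !any(fg)
  list(mask = mask, prob = prob)
}

#' Per-volume intensity normalization
#'
#' Scales intensities by the volume's 99th percentile (robust to hot
#' voxels) and clips to \[0, 2\]; the network consumes the result.
#'
#' @param values numeric array.
#' @return Normalized array of the same shape.
#' @export
normalize_volume <- function(values) {
  q <- quantile(values, 0.99, names = FALSE)
  if (q <= 0) return(values * 0)
  pmin(values / q, 2)
}
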