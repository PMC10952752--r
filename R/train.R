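#' Training configuration for the UNet localizer
#'
#' Adam is used with the conventional defaults beta1 = 0.9, beta2 = 0.999.
#' The learning rate defaults to 1e-3, a standard Adam magnitude for UNets
#' at this scale. Augmentation (random axis flips and additive Gaussian
#' noise) is off by default — the synthetic scene generator already
#' randomizes position, size and noise — and can be enabled per run.
#'
#' @param epochs number of passes over the training set, >= 1.
#' @param learning_rate Adam step size, > 0.
#' @param beta1,beta2 Adam moment decay rates, in (0, 1).
#' @param batch_size volumes per gradient step (accumulated), >= 1.
#' @param seed integer seed controlling shuffling and augmentation.
#' @param augment_flip randomly flip volumes along each axis.
#' @param augment_noise_sd sd of additive Gaussian noise on the normalized
#'   intensities (0 disables).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 4L, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, batch_size = 1L,
                         seed = 0L, augment_flip = FALSE,
                         augment_noise_sd = 0) {
  if (epochs < 1L) abort("`epochs` must be >= 1", class = "fetaltrack_argument_error")
  if (learning_rate <= 0) abort("`learning_rate` must be > 0",
                                class = "fetaltrack_argument_error")
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1) {
    abort("`beta1` and `beta2` must lie in (0, 1)",
          class = "fetaltrack_argument_error")
  }
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment_flip = isTRUE(augment_flip),
                 augment_noise_sd = augment_noise_sd),
            class = "train_config")
}

# one Adam step over a named list of gradients; state carries m, v, t
adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      cfg$learning_rate * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + 1e-8)
  }
  list(params = params, state = state)
}

sample_xt <- function(sample) {
  vol <- sample$volume
  msk <- sample$mask
  x <- normalize_volume(vol$values)
  t2 <- cbind(as.numeric(!msk$values), as.numeric(msk$values))
  list(x = x, t = t2, truth = msk$values)
}

#' Train the UNet localizer with the generalized Dice loss
#'
#' Minimizes [generalized_dice_loss()] with Adam. Deterministic for a fixed
#' `config$seed`. Returns the fitted model plus a per-epoch history of mean
#' training GDL and mean validation Dice (foreground class of the argmax
#' mask against the ground truth).
#'
#' @param train_set,val_set lists of samples; each sample is a list with
#'   `volume` (a [volume_grid()]) and `mask` (a [binary_mask()]), as
#'   produced by [synth_head_dataset()]. `val_set` may be empty.
#' @param config a [train_config()].
#' @param model optionally a pre-built [build_localizer_network()] model
#'   (default: a fresh `"tiny"`-profile network seeded from the config).
#' @param verbose print per-epoch progress.
#' @return An object of class `localizer_fit`: list with `model` and
#'   `history` (tibble: epoch, train_gdl, val_dsc).
#' @export
train_localizer <- function(train_set, val_set = list(),
                            config = train_config(), model = NULL,
                            verbose = FALSE) {
  if (length(train_set) == 0) {
    abort("`train_set` must be non-empty", class = "fetaltrack_argument_error")
  }
  if (is.null(model)) {
    model <- build_localizer_network(network_spec("tiny"), seed = config$seed)
  }
  edge <- model$spec$input_edge
  for (s in c(train_set, val_set)) {
    if (any(dim(s$volume$values) != edge)) {
      abort(sprintf("all samples must be on the network's %d^3 grid", edge),
            class = "fetaltrack_argument_error")
    }
  }
  state <- list(m = list(), v = list(), t = 0L)
  history <- vector("list", config$epochs)
  with_preserved_seed({
    set.seed(config$seed)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(train_set))
      losses <- numeric(0)
      acc <- NULL
      acc_n <- 0L
      for (si in ord) {
        s <- sample_xt(train_set[[si]])
        x <- s$x
        t2 <- s$t
        if (config$augment_flip || config$augment_noise_sd > 0) {
          dd <- dim(x)
          tv <- array(t2[, 2], dd)
          if (config$augment_flip) {
            for (a in 1:3) {
              if (runif(1) < 0.5) {
                idx <- rev(seq_len(dd[a]))
                x <- switch(a, x[idx, , , drop = FALSE],
                            x[, idx, , drop = FALSE], x[, , idx, drop = FALSE])
                tv <- switch(a, tv[idx, , , drop = FALSE],
                             tv[, idx, , drop = FALSE], tv[, , idx, drop = FALSE])
              }
            }
            dim(x) <- dd
            dim(tv) <- dd
          }
          if (config$augment_noise_sd > 0) {
            x <- x + array(rnorm(length(x), 0, config$augment_noise_sd), dd)
          }
          t2 <- cbind(as.numeric(tv == 0), as.numeric(tv))
        }
        fw <- unet_forward(model, x, keep_cache = TRUE)
        p <- matrix(fw$probs, ncol = ncol(t2))
        losses <- c(losses, 1 - 2 * gdl_ratio(p, t2))
        dP <- gdl_gradient(p, t2)
        g <- unet_backward(model, fw, dP)
        acc <- if (is.null(acc)) g else mapply(`+`, acc, g, SIMPLIFY = FALSE)
        acc_n <- acc_n + 1L
        if (acc_n >= config$batch_size) {
          if (config$batch_size > 1L) {
            acc <- lapply(acc, `/`, acc_n)
          }
          upd <- adam_step(model$params, acc, state, config)
          model$params <- upd$params
          state <- upd$state
          acc <- NULL
          acc_n <- 0L
        }
      }
      if (!is.null(acc)) {
        acc <- lapply(acc, `/`, acc_n)
        upd <- adam_step(model$params, acc, state, config)
        model$params <- upd$params
        state <- upd$state
      }
      val_dsc <- NA_real_
      if (length(val_set) > 0) {
        dscs <- vapply(val_set, function(vs) {
          s <- sample_xt(vs)
          fw <- unet_forward(model, s$x, keep_cache = FALSE)
          fg <- fw$probs[, , , 2] > fw$probs[, , , 1]
          dice(fg, s$truth)
        }, numeric(1))
        val_dsc <- mean(dscs)
      }
      history[[epoch]] <- tibble(epoch = epoch,
                                 train_gdl = mean(losses),
                                 val_dsc = val_dsc)
      if (verbose) {
        message(sprintf("epoch %d: train GDL %.4f, val DSC %s", epoch,
                        mean(losses),
                        if (is.na(val_dsc)) "-" else sprintf("%.4f", val_dsc)))
      }
    }
  })
  model$trained_epochs <- model$trained_epochs + config$epochs
  structure(list(model = model, history = bind_rows(history), config = config),
            class = "localizer_fit")
}

# 2*num/den of the GDL: kept separate so the loss shares code with its test
gdl_ratio <- function(p, t) {
  tk <- colSums(t)
  w <- ifelse(tk > 0, 1 / tk^2, 0)
  den <- sum(w * (colSums(p) + tk))
  if (den == 0) return(0.5)
  sum(w * colSums(p * t)) / den
}

#' @export
print.localizer_fit <- function(x, ...) {
  cat(sprintf("<localizer_fit> %d epochs; final train GDL %.4f, val DSC %s\n",
              nrow(x$history), tail(x$history$train_gdl, 1),
              if (is.na(tail(x$history$val_dsc, 1))) "-"
              else sprintf("%.4f", tail(x$history$val_dsc, 1))))
  invisible(x)
}

#' @export
tidy.localizer_fit <- function(x, ...) x$history

#' @export
glance.localizer_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history),
         final_train_gdl = tail(x$history$train_gdl, 1),
         final_val_dsc = tail(x$history$val_dsc, 1),
         seed = x$config$seed)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the architecture spec, the
#' weights and the seed provenance.
#'
#' @param model a [unet3d] (or a `localizer_fit`, whose model is taken).
#' @param path checkpoint file path.
#' @return `load_checkpoint()` returns the [unet3d].
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "localizer_fit")) model <- model$model
  stopifnot(inherits(model, "unet3d"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("checkpoint '%s' does not exist", path),
          class = "fetaltrack_io_error")
  }
  model <- readRDS(path)
  if (!inherits(model, "unet3d")) {
    abort(sprintf("'%s' is not a localizer checkpoint", path),
          class = "fetaltrack_format_error")
  }
  model
}
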