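#' Per-voxel class probability maps and one-hot label maps
#'
#' A `probability_map` stores the network's per-class probability field
#' (per-voxel values in \[0, 1\] summing to 1 across classes within 1e-5);
#' a `label_map` stores a one-hot target. Class 1 is background, class 2
#' foreground (the brain/target) in all two-class configurations.
#'
#' @param probs 4D array (x, y, z, class) of probabilities.
#' @param onehot 4D array (x, y, z, class) of 0/1 with exactly one 1 per voxel.
#' @param geometry a [grid_geometry()].
#' @return An object of class `probability_map` or `label_map`.
#' @export
probability_map <- function(probs, geometry) {
  probs <- as.array(probs)
  d <- dim(probs)
  if (length(d) != 4L || !identical(d[1:3], as.integer(geometry$shape))) {
    abort("`probs` must be (x, y, z, class) matching the geometry",
          class = "fetaltrack_argument_error")
  }
  sums <- rowSums(matrix(probs, ncol = d[4]))
  if (any(abs(sums - 1) > 1e-5) || any(probs < -1e-8) || any(probs > 1 + 1e-8)) {
    abort("per-voxel class probabilities must lie in [0,1] and sum to 1",
          class = "fetaltrack_argument_error")
  }
  structure(list(geometry = geometry, probs = probs),
            class = "probability_map")
}

#' @rdname probability_map
#' @export
label_map <- function(onehot, geometry) {
  onehot <- as.array(onehot)
  d <- dim(onehot)
  if (length(d) != 4L || !identical(d[1:3], as.integer(geometry$shape))) {
    abort("`onehot` must be (x, y, z, class) matching the geometry",
          class = "fetaltrack_argument_error")
  }
  m <- matrix(onehot, ncol = d[4])
  if (!all(m %in% c(0, 1)) || any(rowSums(m) != 1)) {
    abort("`onehot` must have exactly one 1 per voxel",
          class = "fetaltrack_argument_error")
  }
  structure(list(geometry = geometry, onehot = onehot), class = "label_map")
}

#' Convert a binary mask to a two-class one-hot label map
#'
#' @param mask a [binary_mask()].
#' @return A [label_map()] with class 1 = background, class 2 = foreground.
#' @export
mask_to_label_map <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$values)
  onehot <- array(0, dim = c(d, 2L))
  onehot[, , , 1] <- !mask$values
  onehot[, , , 2] <- mask$values
  label_map(onehot, mask$geometry)
}

as_prob_matrix <- function(x) {
  if (inherits(x, "probability_map")) {
    matrix(x$probs, ncol = dim(x$probs)[4])
  } else if (is.array(x) && length(dim(x)) == 4L) {
    matrix(x, ncol = dim(x)[4])
  } else {
    abort("expected a probability_map or a 4D array",
          class = "fetaltrack_argument_error")
  }
}

as_label_matrix <- function(x) {
  if (inherits(x, "label_map")) {
    matrix(x$onehot, ncol = dim(x$onehot)[4])
  } else if (inherits(x, "binary_mask")) {
    cbind(as.numeric(!x$values), as.numeric(x$values))
  } else if (is.array(x) && length(dim(x)) == 4L) {
    matrix(x, ncol = dim(x)[4])
  } else {
    abort("expected a label_map, binary_mask or 4D array",
          class = "fetaltrack_argument_error")
  }
}

#' Generalized Dice loss
#'
#' The multi-class Dice-based training objective
#' `L = 1 - 2 * sum_k w_k sum_n p_kn t_kn / sum_k w_k sum_n (p_kn + t_kn)`
#' with inverse-squared-volume class weights `w_k = 1 / (sum_n t_kn)^2`,
#' where `p_kn` is the predicted probability of class k at voxel n and
#' `t_kn` the one-hot target. Balances classes of very different sizes —
#' here a small brain against a large background. Classes absent from the
#' target (`sum_n t_kn = 0`), for which the weight diverges, are skipped.
#' The value lies in \[0, 1\] and is 0 exactly for a perfect one-hot
#' prediction with all classes present.
#'
#' @param pred a [probability_map()] or 4D (x, y, z, class) array.
#' @param target a [label_map()], [binary_mask()] or 4D one-hot array.
#' @return The scalar loss.
#' @examples
#' g <- grid_geometry(c(2, 2, 2), 1)
#' t <- array(0, c(2, 2, 2, 2)); t[, , , 1] <- 1
#' t[1, 1, 1, ] <- c(0, 1); t[2, 1, 1, ] <- c(0, 1)  # 2 foreground voxels
#' p <- array(0, c(2, 2, 2, 2)); p[, , , 1] <- 1      # all-background guess
#' generalized_dice_loss(p, t)  # 0.625
#' @export
generalized_dice_loss <- function(pred, target) {
  p <- as_prob_matrix(pred)
  t <- as_label_matrix(target)
  if (!identical(dim(p), dim(t))) {
    abort("`pred` and `target` must have identical voxel grids and classes",
          class = "fetaltrack_argument_error")
  }
  if (inherits(pred, "probability_map") && inherits(target, "label_map") &&
      !geometry_equal(pred$geometry, target$geometry)) {
    abort("`pred` and `target` geometries differ",
          class = "fetaltrack_argument_error")
  }
  tk <- colSums(t)
  present <- tk > 0
  w <- ifelse(present, 1 / tk^2, 0)
  num <- sum(w * colSums(p * t))
  den <- sum(w * (colSums(p) + tk))
  if (den == 0) return(0)
  1 - 2 * num / den
}

# gradient of the GDL wrt p (same matrix layout), absent classes skipped
gdl_gradient <- function(p, t) {
  tk <- colSums(t)
  w <- ifelse(tk > 0, 1 / tk^2, 0)
  num <- sum(w * colSums(p * t))
  den <- sum(w * (colSums(p) + tk))
  if (den == 0) return(matrix(0, nrow(p), ncol(p)))
  # dL/dp_kn = -2 w_k (t_kn * den - num) / den^2
  gw <- matrix(w, nrow(p), ncol(p), byrow = TRUE)
  -2 * gw * (t * den - num) / den^2
}
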