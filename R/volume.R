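#' Image volumes and binary masks on a world-anchored grid
#'
#' `volume_grid()` holds one repetition's image (non-negative intensities)
#' together with its [grid_geometry()], the repetition index (1-based) and,
#' for multi-echo series, the echo time in ms. `binary_mask()` holds a
#' segmentation on the same kind of grid.
#'
#' @param values numeric (or logical, for masks) 3D array; its `dim` must
#'   equal `geometry$shape`.
#' @param geometry a [grid_geometry()].
#' @param repetition 1-based repetition index of the volume in its series.
#' @param te_ms echo time in milliseconds, or `NA` when not applicable.
#' @return An object of class `volume_grid` or `binary_mask`.
#' @export
volume_grid <- function(values, geometry, repetition = 1L, te_ms = NA_real_) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(geometry$shape))) {
    abort("`values` dimensions must equal `geometry$shape`",
          class = "fetaltrack_argument_error")
  }
  if (!is.na(te_ms) && te_ms <= 0) {
    abort("`te_ms` must be > 0", class = "fetaltrack_argument_error")
  }
  structure(list(geometry = geometry, values = values,
                 repetition = as.integer(repetition), te_ms = as.numeric(te_ms)),
            class = "volume_grid")
}

#' @rdname volume_grid
#' @export
binary_mask <- function(values, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(geometry$shape))) {
    abort("`values` dimensions must equal `geometry$shape`",
          class = "fetaltrack_argument_error")
  }
  storage.mode(values) <- "logical"
  structure(list(geometry = geometry, values = values), class = "binary_mask")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> rep %d%s, %s voxels, intensity [%.3g, %.3g]\n",
              x$repetition,
              if (is.na(x$te_ms)) "" else sprintf(" TE %g ms", x$te_ms),
              paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  print(x$geometry)
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground\n",
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  print(x$geometry)
  invisible(x)
}

mask_values <- function(x) {
  if (inherits(x, "binary_mask")) x$values
  else if (is.logical(x)) x
  else abort("expected a `binary_mask` or a logical array",
             class = "fetaltrack_argument_error")
}

#' Pad and crop a volume or mask onto a fixed cubic grid
#'
#' Maps any input stack or mask to a `target_edge`^3 voxel grid (128 by
#' default, the network's input grid) by centered zero-padding and/or
#' cropping per axis. Voxels retained from the input keep their intensities
#' and their world coordinates: the output geometry's `fov_center` is moved
#' to compensate for any asymmetric placement. The padding value is 0
#' (air/background). Anisotropic inputs are first resampled to the smallest
#' voxel spacing (trilinear for images, nearest-neighbour for masks).
#'
#' @param x a [volume_grid()] or [binary_mask()].
#' @param target_edge positive integer edge length of the output grid.
#' @return An object of the same class as `x` on a `target_edge`^3 grid.
#' @export
pad_crop_to_grid <- function(x, target_edge = 128L) {
  target_edge <- as.integer(target_edge)
  if (is.na(target_edge) || target_edge < 1L) {
    abort("`target_edge` must be a positive integer",
          class = "fetaltrack_argument_error")
  }
  if (!inherits(x, "volume_grid") && !inherits(x, "binary_mask")) {
    abort("`x` must be a volume_grid or binary_mask",
          class = "fetaltrack_argument_error")
  }
  if (diff(range(x$geometry$spacing)) > 1e-9) {
    x <- resample_isotropic(x)
  }
  g <- x$geometry
  n <- g$shape
  tgt <- rep(target_edge, 3L)
  # centered placement: output index j holds input index j - off
  off <- ifelse(tgt >= n, (tgt - n) %/% 2L, -((n - tgt) %/% 2L))
  is_mask <- inherits(x, "binary_mask")
  out <- array(if (is_mask) FALSE else 0, dim = tgt)
  src <- lapply(1:3, function(a) {
    i <- seq_len(n[a])
    i[i + off[a] >= 1L & i + off[a] <= tgt[a]]
  })
  dst <- lapply(1:3, function(a) src[[a]] + off[a])
  out[dst[[1]], dst[[2]], dst[[3]]] <- x$values[src[[1]], src[[2]], src[[3]]]
  # keep world coordinates of the retained region:
  # fc_new = fc_old + spacing * ((tgt+1)/2 - (n+1)/2 - off)
  fc_new <- g$fov_center + g$spacing * ((tgt + 1) / 2 - (n + 1) / 2 - off)
  gg <- grid_geometry(tgt, g$spacing, fc_new)
  if (is_mask) binary_mask(out, gg)
  else volume_grid(out, gg, repetition = x$repetition, te_ms = x$te_ms)
}

#' Resample a volume or mask to isotropic spacing
#'
#' Resamples to the smallest spacing among the three axes, keeping the FOV
#' center fixed and approximately preserving the physical extent. Trilinear
#' interpolation for images, nearest-neighbour for masks.
#'
#' @inheritParams pad_crop_to_grid
#' @param target_spacing isotropic output spacing in mm; defaults to the
#'   smallest input spacing.
#' @return Same class as `x`.
#' @export
resample_isotropic <- function(x, target_spacing = min(x$geometry$spacing)) {
  g <- x$geometry
  if (max(abs(g$spacing - target_spacing)) < 1e-12) return(x)
  new_shape <- pmax(1L, as.integer(round(g$shape * g$spacing / target_spacing)))
  gg <- grid_geometry(new_shape, rep(target_spacing, 3), g$fov_center)
  ax <- axis_world_coords(gg)
  is_mask <- inherits(x, "binary_mask")
  # continuous source indices of each output voxel center, per axis
  src <- lapply(1:3, function(a) {
    (ax[[a]] - g$fov_center[a]) / g$spacing[a] + (g$shape[a] + 1) / 2
  })
  if (is_mask) {
    idx <- lapply(1:3, function(a) pmin(pmax(round(src[[a]]), 1L), g$shape[a]))
    out <- x$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(out) <- new_shape
    return(binary_mask(out, gg))
  }
  lo <- lapply(1:3, function(a) pmin(pmax(floor(src[[a]]), 1L), g$shape[a]))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, g$shape[a]))
  w <- lapply(1:3, function(a) pmin(pmax(src[[a]] - lo[[a]], 0), 1))
  v <- x$values
  out <- array(0, dim = new_shape)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) hi[[1]] else lo[[1]]
    iy <- if (cy) hi[[2]] else lo[[2]]
    iz <- if (cz) hi[[3]] else lo[[3]]
    wx <- if (cx) w[[1]] else 1 - w[[1]]
    wy <- if (cy) w[[2]] else 1 - w[[2]]
    wz <- if (cz) w[[3]] else 1 - w[[3]]
    wt <- outer(outer(wx, wy), wz)
    out <- out + wt * v[ix, iy, iz, drop = FALSE]
  }
  volume_grid(out, gg, repetition = x$repetition, te_ms = x$te_ms)
}
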