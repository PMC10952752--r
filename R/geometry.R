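#' Grid geometry: voxel grid shape, spacing and world-space FOV center
#'
#' A `grid_geometry` ties a voxel grid to scanner (world) coordinates. The
#' package-wide axis convention is x right-to-left, y bottom-to-top and
#' z front-to-back of the bore, all in millimetres. The *center* of the grid
#' is the continuous midpoint index `(shape + 1) / 2` (1-based), so that
#' even-sized grids have a half-voxel-offset center; by construction the
#' world coordinate of that midpoint equals `fov_center` exactly. This is the
#' geometric parameter the feedback loop updates when it recenters the
#' field of view.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric vector of length 3 (or a scalar, recycled), mm per
#'   voxel; all entries > 0. Shipped configurations are isotropic.
#' @param fov_center numeric vector of length 3, world position (mm) of the
#'   continuous grid midpoint.
#'
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(c(64, 64, 64), 3)
#' voxel_to_world(c(32.5, 32.5, 32.5), g)  # the midpoint maps to fov_center
#' @export
grid_geometry <- function(shape, spacing, fov_center = c(0, 0, 0)) {
  shape <- as.integer(round(rep_len(shape, 3L)))
  spacing <- as.numeric(rep_len(spacing, 3L))
  fov_center <- as.numeric(rep_len(fov_center, 3L))
  if (any(shape < 1L)) {
    abort("all `shape` entries must be >= 1", class = "fetaltrack_argument_error")
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("all `spacing` entries must be finite and > 0",
          class = "fetaltrack_argument_error")
  }
  if (any(!is.finite(fov_center))) {
    abort("`fov_center` must be finite", class = "fetaltrack_argument_error")
  }
  structure(list(shape = shape, spacing = spacing, fov_center = fov_center),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %s voxels @ %s mm, FOV center (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$fov_center), collapse = ", ")))
  invisible(x)
}

geometry_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$fov_center - b$fov_center)) <= tol
}

grid_midpoint <- function(geometry) (geometry$shape + 1) / 2

#' Map continuous voxel indices to world coordinates
#'
#' Voxel indices are 1-based and continuous; the grid midpoint
#' `(shape + 1) / 2` maps exactly to `fov_center`:
#' `world = fov_center + spacing * (index - (shape + 1) / 2)`.
#' `world_to_voxel()` is the exact inverse.
#'
#' @param index numeric vector of length 3 or an n x 3 matrix of (possibly
#'   fractional) 1-based voxel indices.
#' @param point numeric vector of length 3 or an n x 3 matrix of world
#'   coordinates (mm).
#' @param geometry a [grid_geometry()].
#' @return A vector of length 3 or an n x 3 matrix, matching the input shape.
#' @export
voxel_to_world <- function(index, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  mid <- grid_midpoint(geometry)
  if (is.matrix(index)) {
    sweep(sweep(index, 2, mid), 2, geometry$spacing, "*") +
      matrix(geometry$fov_center, nrow(index), 3, byrow = TRUE)
  } else {
    geometry$fov_center + geometry$spacing * (as.numeric(index) - mid)
  }
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(point, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  mid <- grid_midpoint(geometry)
  if (is.matrix(point)) {
    sweep(sweep(point, 2, geometry$fov_center), 2, geometry$spacing, "/") +
      matrix(mid, nrow(point), 3, byrow = TRUE)
  } else {
    (as.numeric(point) - geometry$fov_center) / geometry$spacing + mid
  }
}

# world coordinates of all voxel centers, one vector per axis
axis_world_coords <- function(geometry) {
  lapply(1:3, function(a) {
    voxel_axis <- seq_len(geometry$shape[a])
    geometry$fov_center[a] +
      geometry$spacing[a] * (voxel_axis - (geometry$shape[a] + 1) / 2)
  })
}
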