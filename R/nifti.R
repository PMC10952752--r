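#' Read and write volumes as NIfTI
#'
#' Volumes and masks are exchanged as NIfTI-1 files (`.nii` / `.nii.gz`),
#' 4D files being repetition series. The affine written is diagonal in the
#' package's fixed x/y/z axis convention, `world = spacing * (index0) + t`
#' with the translation chosen so that the continuous grid midpoint maps to
#' `fov_center`; all units are millimetres. On reading, spacing is taken
#' from the header pixel dimensions and `fov_center` from the affine's
#' grid-midpoint mapping.
#'
#' @param path file path to a NIfTI image.
#' @param te_ms optional echo time (ms) recorded on the returned volume(s).
#' @return `load_volume()`: a [volume_grid()] for a 3D file, or a list of
#'   [volume_grid()] with `repetition` 1..T for a 4D file.
#' @export
load_volume <- function(path, te_ms = NA_real_) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read NIfTI file: '%s' does not exist", path),
          class = "fetaltrack_io_error")
  }
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) {
                    abort(sprintf("'%s' is not a readable NIfTI file: %s",
                                  path, conditionMessage(e)),
                          class = "fetaltrack_format_error")
                  })
  d <- dim(img)
  if (!(length(d) %in% c(3L, 4L))) {
    abort(sprintf("'%s' has %d dimensions; expected a 3D or 4D payload",
                  path, length(d)),
          class = "fetaltrack_format_error")
  }
  aff <- RNifti::xform(img)
  shape <- d[1:3]
  spacing <- abs(c(aff[1, 1], aff[2, 2], aff[3, 3]))
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  mid0 <- (shape - 1) / 2  # 0-based continuous midpoint, NIfTI convention
  fc <- as.numeric(aff[1:3, 1:3] %*% mid0 + aff[1:3, 4])
  geom <- grid_geometry(shape, spacing, fc)
  arr <- as.array(img)
  if (length(d) == 3L) {
    return(volume_grid(arr, geom, repetition = 1L, te_ms = te_ms))
  }
  lapply(seq_len(d[4]), function(t) {
    volume_grid(arr[, , , t], geom, repetition = t, te_ms = te_ms)
  })
}

#' @rdname load_volume
#' @param x a [volume_grid()], a [binary_mask()] (written as integer 0/1),
#'   or a list of `volume_grid`s sharing one geometry (written as 4D).
#' @return `save_volume()`: the path, invisibly.
#' @export
save_volume <- function(x, path) {
  if (!dir.exists(dirname(path))) {
    abort(sprintf("cannot write '%s': directory does not exist", path),
          class = "fetaltrack_io_error")
  }
  if (inherits(x, "volume_grid")) {
    geom <- x$geometry
    arr <- x$values
  } else if (inherits(x, "binary_mask")) {
    geom <- x$geometry
    arr <- array(as.integer(x$values), dim = dim(x$values))
  } else if (is.list(x) && length(x) > 0 && inherits(x[[1]], "volume_grid")) {
    geom <- x[[1]]$geometry
    for (v in x) {
      if (!geometry_equal(v$geometry, geom)) {
        abort("all volumes in a series must share one geometry",
              class = "fetaltrack_argument_error")
      }
    }
    arr <- array(0, dim = c(geom$shape, length(x)))
    for (t in seq_along(x)) arr[, , , t] <- x[[t]]$values
  } else {
    abort("`x` must be a volume_grid, binary_mask or list of volume_grids",
          class = "fetaltrack_argument_error")
  }
  aff <- diag(4)
  aff[1, 1] <- geom$spacing[1]
  aff[2, 2] <- geom$spacing[2]
  aff[3, 3] <- geom$spacing[3]
  aff[1:3, 4] <- geom$fov_center - geom$spacing * (geom$shape - 1) / 2
  img <- RNifti::asNifti(
    arr,
    list(pixdim = c(-1, geom$spacing, 1, 1, 1, 1), xyzt_units = 2L),
    datatype = if (is.integer(arr)) "int16" else "double"
  )
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    abort(sprintf("failed to write NIfTI file '%s'", path),
          class = "fetaltrack_io_error")
  }
  invisible(path)
}
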