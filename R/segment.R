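#' Intensity-based target segmentation
#'
#' The phantom-path localizer: threshold the volume (Otsu's method when
#' `threshold = "auto"`), keep the single largest 6-connected foreground
#' component, and fill internal holes (background components not connected
#' to the volume border). With `threshold = "auto"` the result is invariant
#' to global positive intensity scaling. An all-zero or constant volume
#' yields an empty mask flagged via `attr(mask, "empty_flag")`.
#'
#' @param volume a [volume_grid()] with finite intensities.
#' @param threshold `"auto"` for Otsu, or a numeric cutoff (foreground is
#'   `values > threshold`).
#' @return A [binary_mask()] with an `empty_flag` attribute.
#' @export
segment_intensity <- function(volume, threshold = "auto") {
  stopifnot(inherits(volume, "volume_grid"))
  v <- volume$values
  if (any(!is.finite(v))) {
    abort("volume intensities must be finite", class = "fetaltrack_argument_error")
  }
  empty <- function() {
    m <- binary_mask(array(FALSE, dim(v)), volume$geometry)
    attr(m, "empty_flag") <- TRUE
    m
  }
  if (identical(threshold, "auto")) {
    if (diff(range(v)) == 0) return(empty())
    threshold <- otsu_threshold(v)
  }
  fg <- v > threshold
  if (!any(fg)) return(empty())
  lab <- cpp_label3d(fg, as.integer(dim(fg)))
  counts <- tabulate(lab[lab > 0L])
  keep <- lab == which.max(counts)
  keep <- fill_holes3d(keep)
  m <- binary_mask(keep, volume$geometry)
  attr(m, "empty_flag") <- FALSE
  m
}

# Otsu's between-class-variance threshold on a 256-bin histogram of the
# data range; returns a cutoff strictly inside the range.
otsu_threshold <- function(v, nbins = 256L) {
  r <- range(v)
  h <- tabulate(pmin(pmax(findInterval(v, seq(r[1], r[2],
                                              length.out = nbins + 1L),
                                       all.inside = TRUE), 1L), nbins), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) * diff(r) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  r[1] + k * diff(r) / nbins  # upper edge of the winning bin
}

# fill internal cavities: background 6-components not touching the border
fill_holes3d <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  lab <- cpp_label3d(bg, as.integer(d))
  border_labels <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ],
                            lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
  border_labels <- border_labels[border_labels > 0L]
  internal <- bg & !(lab %in% border_labels)
  dim(internal) <- d
  mask | internal
}
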