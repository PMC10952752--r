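#' Step-wise translational motion events and trajectories
#'
#' Motion is modeled as controlled rectangular (step) translations of the
#' tracked target: each `motion_event` adds a world-frame step `delta` that
#' is first visible in the volume acquired at `first_visible_repetition`
#' (1-based) and persists thereafter. A `trajectory` is the piecewise
#' constant cumulative offset over a series: the offset at repetition r is
#' the sum of the deltas of all events with `first_visible_repetition <= r`.
#'
#' @param first_visible_repetition 1-based repetition at which the step
#'   first appears in the acquired image.
#' @param delta numeric length 3, world-frame step translation in mm.
#' @return `motion_event()`: an object of class `motion_event`.
#' @export
motion_event <- function(first_visible_repetition, delta) {
  first_visible_repetition <- as.integer(first_visible_repetition)
  delta <- as.numeric(rep_len(delta, 3L))
  if (is.na(first_visible_repetition) || first_visible_repetition < 1L) {
    abort("`first_visible_repetition` must be a repetition index >= 1",
          class = "fetaltrack_argument_error")
  }
  if (any(!is.finite(delta))) {
    abort("`delta` must be finite", class = "fetaltrack_argument_error")
  }
  structure(list(first_visible_repetition = first_visible_repetition,
                 delta = delta),
            class = "motion_event")
}

#' @rdname motion_event
#' @param events list of [motion_event()]s (possibly empty).
#' @param n_repetitions series length, >= 1.
#' @return `step_trajectory()`: an object of class `trajectory` with fields
#'   `n_repetitions` and `offsets` (an `n_repetitions` x 3 matrix of mm).
#' @examples
#' tr <- step_trajectory(list(motion_event(7, c(9, 0, 0))), 12)
#' tr$offsets[6, ]  # still zero
#' tr$offsets[7, ]  # (9, 0, 0) from repetition 7 onwards
#' @export
step_trajectory <- function(events = list(), n_repetitions) {
  n_repetitions <- as.integer(n_repetitions)
  if (is.na(n_repetitions) || n_repetitions < 1L) {
    abort("`n_repetitions` must be >= 1", class = "fetaltrack_argument_error")
  }
  if (inherits(events, "motion_event")) events <- list(events)
  offsets <- matrix(0, n_repetitions, 3,
                    dimnames = list(NULL, c("dx_mm", "dy_mm", "dz_mm")))
  for (ev in events) {
    if (!inherits(ev, "motion_event")) {
      abort("`events` must be a list of motion_event objects",
            class = "fetaltrack_argument_error")
    }
    if (ev$first_visible_repetition > n_repetitions) {
      abort(sprintf(
        "motion event at repetition %d is outside the %d-repetition series",
        ev$first_visible_repetition, n_repetitions),
        class = "fetaltrack_argument_error")
    }
    r <- ev$first_visible_repetition:n_repetitions
    offsets[r, ] <- offsets[r, , drop = FALSE] +
      matrix(ev$delta, length(r), 3, byrow = TRUE)
  }
  structure(list(n_repetitions = n_repetitions, offsets = offsets,
                 events = events),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d repetitions, %d motion events\n",
              x$n_repetitions, length(x$events)))
  invisible(x)
}

#' @export
tidy.trajectory <- function(x, ...) {
  tibble(repetition = seq_len(x$n_repetitions),
         dx_mm = x$offsets[, 1], dy_mm = x$offsets[, 2], dz_mm = x$offsets[, 3])
}

trajectory_offset <- function(trajectory, repetition) {
  if (repetition < 1L || repetition > trajectory$n_repetitions) {
    abort(sprintf("repetition %d outside trajectory of length %d",
                  repetition, trajectory$n_repetitions),
          class = "fetaltrack_argument_error")
  }
  trajectory$offsets[repetition, ]
}
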