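#' Center of mass of a binary mask in world coordinates
#'
#' The unweighted mean of the foreground voxel indices, mapped through
#' [voxel_to_world()] under the mask's own geometry — so the result is in
#' the scanner frame and directly comparable across repetitions whose FOV
#' centers differ.
#'
#' @param mask a [binary_mask()].
#' @return Numeric length 3 (mm); all-`NA` with attribute `empty = TRUE`
#'   for an empty mask (the loop treats it as a missing observation,
#'   never an error).
#' @export
center_of_mass <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$values)
  if (length(idx) == 0) {
    out <- c(NA_real_, NA_real_, NA_real_)
    attr(out, "empty") <- TRUE
    return(out)
  }
  ijk <- arrayInd(idx, dim(mask$values))
  voxel_to_world(colMeans(ijk), mask$geometry)
}

#' Closed-loop controller configuration
#'
#' `latency_repetitions` is the feedback delay: a correction computed from
#' the image at repetition n takes effect in the FOV of repetition
#' n + latency, so an object step first visible at repetition r is
#' corrected in the image acquired at r + latency (2 by default, the
#' behavior of the deployed system). The plausibility gate suppresses (and
#' flags) corrections derived from masks whose volume falls outside
#' `[min_volume_ml, max_volume_ml]` — a mis-segmentation guard motivated
#' by intensity-similar structures such as the stomach; set the bounds to
#' `c(0, Inf)` to disable it. `max_shift_mm` clips each correction per
#' axis (default: half the FOV extent, so a single bad update cannot throw
#' the FOV off the scene).
#'
#' @param latency_repetitions integer feedback latency >= 1.
#' @param localizer `"intensity"`, a [unet3d] model, or a function
#'   `function(volume) -> binary_mask`.
#' @param min_volume_ml,max_volume_ml plausible target volume bounds (ml).
#' @param max_shift_mm per-axis clip for one FOV update (`NULL`: half the
#'   FOV extent, resolved inside the loop).
#' @param min_update_mm corrections whose largest per-axis magnitude falls
#'   below this deadband are suppressed (`NULL`: half a voxel, resolved
#'   inside the loop) — sub-voxel rasterization and noise residuals should
#'   not retrigger FOV updates.
#' @param tracking_te_index which configured echo is used for tracking.
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(latency_repetitions = 2L, localizer = "intensity",
                        min_volume_ml = 10, max_volume_ml = 1000,
                        max_shift_mm = NULL, min_update_mm = NULL,
                        tracking_te_index = 1L) {
  latency_repetitions <- as.integer(latency_repetitions)
  if (is.na(latency_repetitions) || latency_repetitions < 1L) {
    abort("`latency_repetitions` must be >= 1",
          class = "fetaltrack_argument_error")
  }
  structure(list(latency_repetitions = latency_repetitions,
                 localizer = localizer,
                 min_volume_ml = min_volume_ml, max_volume_ml = max_volume_ml,
                 max_shift_mm = max_shift_mm, min_update_mm = min_update_mm,
                 tracking_te_index = as.integer(tracking_te_index)),
            class = "loop_config")
}

#' FOV controller state
#'
#' Tracks the per-repetition FOV centers and the queue of pending shifts.
#' Exposed for testing the controller arithmetic; [run_closed_loop()]
#' manages it internally.
#'
#' @param initial_center world FOV center (mm) of the first repetition.
#' @return An object of class `fov_state`.
#' @export
new_fov_state <- function(initial_center = c(0, 0, 0)) {
  structure(list(centers = matrix(numeric(0), 0, 3),
                 current = as.numeric(initial_center),
                 pending = tibble(apply_at = integer(0), sx = numeric(0),
                                  sy = numeric(0), sz = numeric(0))),
            class = "fov_state")
}

# advance to repetition n: apply due pending shifts, record the center
fov_advance <- function(fs, n) {
  due <- fs$pending$apply_at <= n
  shift <- c(0, 0, 0)
  if (any(due)) {
    shift <- c(sum(fs$pending$sx[due]), sum(fs$pending$sy[due]),
               sum(fs$pending$sz[due]))
    fs$current <- fs$current + shift
    fs$pending <- fs$pending[!due, , drop = FALSE]
  }
  fs$centers <- rbind(fs$centers, fs$current)
  list(fs = fs, center = fs$current, shift_applied = shift)
}

pending_sum <- function(fs) {
  c(sum(fs$pending$sx), sum(fs$pending$sy), sum(fs$pending$sz))
}

#' Queue a FOV correction
#'
#' Queues `correction` to take effect `latency` repetitions after the
#' repetition whose image it was computed from: computed at n, the FOV
#' center of repetitions >= n + latency includes the shift. Corrections
#' queued for the same repetition sum. A zero correction leaves the state
#' unchanged.
#'
#' @param fs a [new_fov_state()].
#' @param correction numeric length 3 (mm).
#' @param computed_at repetition index whose image produced the correction.
#' @param latency feedback latency in repetitions.
#' @return The updated `fov_state`.
#' @export
apply_fov_update <- function(fs, correction, computed_at, latency = 2L) {
  stopifnot(inherits(fs, "fov_state"))
  correction <- as.numeric(rep_len(correction, 3L))
  if (any(!is.finite(correction))) {
    abort("`correction` must be finite", class = "fetaltrack_argument_error")
  }
  if (all(correction == 0)) return(fs)
  fs$pending <- bind_rows(fs$pending,
                          tibble(apply_at = as.integer(computed_at + latency),
                                 sx = correction[1], sy = correction[2],
                                 sz = correction[3]))
  fs
}

#' Displacement of the CoM between repetitions n and n - 2
#'
#' The deployed system's feedback quantity: the world-frame CoM difference between
#' time points n and n - 2, each CoM computed under its own repetition's
#' FOV geometry. `NULL` during warm-up (n < 3) or when either CoM is
#' missing (empty mask).
#'
#' @param records the audit tibble built by [run_closed_loop()] (needs
#'   columns `com_x/y/z` for repetitions up to `n`).
#' @param n repetition index (1-based).
#' @param gap how many repetitions back to difference (default 2).
#' @return Numeric length 3 with attributes `from`/`to`, or `NULL`.
#' @export
estimate_displacement <- function(records, n, gap = 2L) {
  if (n - gap < 1L || n > nrow(records)) return(NULL)
  a <- unlist(records[n, c("com_x", "com_y", "com_z")], use.names = FALSE)
  b <- unlist(records[n - gap, c("com_x", "com_y", "com_z")], use.names = FALSE)
  if (any(is.na(a)) || any(is.na(b))) return(NULL)
  d <- a - b
  attr(d, "from") <- as.integer(n - gap)
  attr(d, "to") <- as.integer(n)
  d
}

#' Pending-aware recentering correction
#'
#' The correction actually driving the FOV: the offset of the current CoM
#' from the current FOV center, minus the sum of already queued but
#' not-yet-applied shifts (so a displacement that remains visible while
#' its correction is still in flight is not corrected twice), clipped
#' per axis to `max_shift_mm`. Zero when the CoM is missing.
#'
#' @param records audit tibble up to repetition `n` (columns `com_*`).
#' @param fs the current [new_fov_state()].
#' @param n repetition index.
#' @param max_shift_mm per-axis clip (mm).
#' @return Numeric length 3 (mm).
#' @export
compute_correction <- function(records, fs, n, max_shift_mm = Inf) {
  com <- unlist(records[n, c("com_x", "com_y", "com_z")], use.names = FALSE)
  if (any(is.na(com))) return(c(0, 0, 0))
  corr <- (com - fs$centers[n, ]) - pending_sum(fs)
  pmin(pmax(corr, -max_shift_mm), max_shift_mm)
}

resolve_localizer <- function(localizer) {
  if (is.function(localizer)) return(localizer)
  if (inherits(localizer, "unet3d")) {
    model <- localizer
    return(function(volume) predict_mask(model, volume)$mask)
  }
  if (identical(localizer, "intensity")) {
    return(function(volume) segment_intensity(volume))
  }
  abort("`localizer` must be \"intensity\", a unet3d model or a function",
        class = "fetaltrack_argument_error")
}

#' Run the closed-loop tracking simulation
#'
#' The in-silico counterpart of the scanner feedback loop. For each
#' repetition: acquire at the controller's current FOV, localize the
#' target, take its world-frame CoM, report the n vs n-2 displacement,
#' compute the pending-aware recentering correction, and queue the FOV
#' update to take effect `latency_repetitions` later. A localizer failure
#' or empty mask on one repetition flags the record and holds the last
#' FOV; implausible mask volumes (outside the configured bounds) suppress
#' the correction and are flagged.
#'
#' @param scene a [world_scene()].
#' @param trajectory a [step_trajectory()] trajectory (ground truth motion).
#' @param acq an [acquisition_config()].
#' @param loop a [loop_config()].
#' @param localizer overrides `loop$localizer` when non-`NULL`.
#' @param fov_center initial world FOV center.
#' @param keep_volumes also return the acquired volumes (memory permitting).
#' @return A `tracking_run`: tibble with one row per repetition —
#'   `repetition`, FOV center `fov_x/y/z`, world CoM `com_x/y/z`,
#'   image-frame offset `resid_x/y/z` (CoM minus FOV center),
#'   `mask_voxels`, displacement `disp_x/y/z` (n vs n-2), correction
#'   `corr_x/y/z` computed from this repetition, `shift_x/y/z` applied at
#'   this repetition, and `empty_flag` / `implausible_flag` — with the
#'   configuration in attributes.
#' @export
run_closed_loop <- function(scene, trajectory, acq, loop = loop_config(),
                            localizer = NULL, fov_center = c(0, 0, 0),
                            keep_volumes = FALSE) {
  stopifnot(inherits(scene, "world_scene"), inherits(trajectory, "trajectory"),
            inherits(acq, "acquisition_config"), inherits(loop, "loop_config"))
  loc_fn <- resolve_localizer(localizer %||% loop$localizer)
  n_rep <- trajectory$n_repetitions
  te <- acq$te_ms[min(loop$tracking_te_index, length(acq$te_ms))]
  max_shift <- loop$max_shift_mm %||% (acq$edge * acq$spacing_mm / 2)
  min_update <- loop$min_update_mm %||% (acq$spacing_mm / 2)
  voxel_ml <- acq$spacing_mm^3 / 1000
  fs <- new_fov_state(fov_center)
  rows <- vector("list", n_rep)
  volumes <- if (keep_volumes) vector("list", n_rep)
  rec <- tibble(repetition = integer(0), com_x = numeric(0),
                com_y = numeric(0), com_z = numeric(0))
  for (n in seq_len(n_rep)) {
    adv <- fov_advance(fs, n)
    fs <- adv$fs
    geom <- grid_geometry(rep(acq$edge, 3), rep(acq$spacing_mm, 3), adv$center)
    vol <- acquire_repetition(scene, trajectory, geom, n, te, acq)
    if (keep_volumes) volumes[[n]] <- vol
    mask <- tryCatch(loc_fn(vol), error = function(e) NULL)
    failed <- is.null(mask)
    if (failed) {
      com <- c(NA_real_, NA_real_, NA_real_)
      voxels <- 0L
    } else {
      com <- center_of_mass(mask)
      voxels <- sum(mask$values)
    }
    empty <- failed || isTRUE(attr(com, "empty"))
    vol_ml <- voxels * voxel_ml
    implausible <- !empty &&
      (vol_ml < loop$min_volume_ml || vol_ml > loop$max_volume_ml)
    rec <- bind_rows(rec, tibble(repetition = n, com_x = com[1],
                                 com_y = com[2], com_z = com[3]))
    disp <- estimate_displacement(rec, n)
    corr <- c(0, 0, 0)
    if (!empty && !implausible) {
      corr <- compute_correction(rec, fs, n, max_shift)
      if (max(abs(corr)) < min_update) corr <- c(0, 0, 0)  # deadband
      fs <- apply_fov_update(fs, corr, n, loop$latency_repetitions)
    }
    rows[[n]] <- tibble(
      repetition = n,
      fov_x = adv$center[1], fov_y = adv$center[2], fov_z = adv$center[3],
      com_x = com[1], com_y = com[2], com_z = com[3],
      resid_x = com[1] - adv$center[1], resid_y = com[2] - adv$center[2],
      resid_z = com[3] - adv$center[3],
      mask_voxels = as.integer(voxels),
      disp_x = if (is.null(disp)) NA_real_ else disp[1],
      disp_y = if (is.null(disp)) NA_real_ else disp[2],
      disp_z = if (is.null(disp)) NA_real_ else disp[3],
      corr_x = corr[1], corr_y = corr[2], corr_z = corr[3],
      shift_x = adv$shift_applied[1], shift_y = adv$shift_applied[2],
      shift_z = adv$shift_applied[3],
      empty_flag = empty, implausible_flag = implausible
    )
  }
  out <- bind_rows(rows)
  attr(out, "scene") <- scene
  attr(out, "trajectory") <- trajectory
  attr(out, "acq") <- acq
  attr(out, "loop") <- loop
  if (keep_volumes) attr(out, "volumes") <- volumes
  class(out) <- c("tracking_run", class(out))
  out
}

#' @export
tidy.tracking_run <- function(x, ...) {
  out <- x
  attributes(out)[c("scene", "trajectory", "acq", "loop", "volumes")] <- NULL
  class(out) <- setdiff(class(out), "tracking_run")
  as_tibble(out)
}

#' @export
glance.tracking_run <- function(x, ...) {
  shifts <- abs(x$shift_x) + abs(x$shift_y) + abs(x$shift_z) > 0
  tibble(
    n_repetitions = nrow(x),
    n_shifts = sum(shifts),
    n_empty = sum(x$empty_flag),
    n_implausible = sum(x$implausible_flag),
    max_abs_shift_mm = if (any(shifts)) {
      max(abs(c(x$shift_x, x$shift_y, x$shift_z)))
    } else 0,
    final_resid_mm = sqrt(sum(unlist(
      x[nrow(x), c("resid_x", "resid_y", "resid_z")])^2))
  )
}

#' Write the loop audit trail to disk
#'
#' @param run a `tracking_run` from [run_closed_loop()].
#' @param path_csv,path_json output paths (`NULL` to skip either).
#' @return Invisibly, the tidied records tibble.
#' @export
write_audit_trail <- function(run, path_csv = NULL, path_json = NULL) {
  rec <- tidy(run)
  if (!is.null(path_csv)) write.csv(rec, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(rec, path_json, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(rec)
}
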