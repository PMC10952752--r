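#' Overlap metrics between binary masks
#'
#' `dice()` is the Dice similarity coefficient `2|A∩B| / (|A| + |B|)`;
#' `iou()` the intersection-over-union `|A∩B| / |A∪B|`. Both are symmetric
#' and defined as 1 when both masks are empty (perfect agreement) and 0
#' when exactly one is empty. For binary masks the two are linked exactly
#' by `IoU = DSC / (2 - DSC)`.
#'
#' @param a,b [binary_mask()]s on the same geometry, or logical arrays of
#'   the same shape.
#' @return A value in \[0, 1\].
#' @export
dice <- function(a, b) {
  av <- mask_values(a)
  bv <- mask_values(b)
  check_same_grid(a, b, av, bv)
  na <- sum(av)
  nb <- sum(bv)
  if (na + nb == 0) return(1)
  2 * sum(av & bv) / (na + nb)
}

#' @rdname dice
#' @export
iou <- function(a, b) {
  av <- mask_values(a)
  bv <- mask_values(b)
  check_same_grid(a, b, av, bv)
  un <- sum(av | bv)
  if (un == 0) return(1)
  sum(av & bv) / un
}

check_same_grid <- function(a, b, av, bv) {
  if (!identical(dim(av), dim(bv))) {
    abort("masks must share one voxel grid", class = "fetaltrack_argument_error")
  }
  if (inherits(a, "binary_mask") && inherits(b, "binary_mask") &&
      !geometry_equal(a$geometry, b$geometry)) {
    abort("mask geometries differ", class = "fetaltrack_argument_error")
  }
  invisible(TRUE)
}

#' Per-axis mean squared error between CoM trajectories
#'
#' Squared millimetre differences between predicted and ground-truth CoM
#' coordinates, averaged across repetitions, with the sd of the squared
#' differences. Pairs with a missing entry on either side are excluded.
#' Both the MSE (mm^2) and its square root (RMSE, mm) are reported, since
#' printed "MSE in mm" conventions differ.
#'
#' @param predicted,truth n x 3 matrices (or data frames with 3 columns)
#'   of world CoM coordinates, equal row counts.
#' @return A tibble with columns `axis`, `n`, `mse`, `mse_sd`, `rmse`.
#' @export
com_mse <- function(predicted, truth) {
  p <- as.matrix(predicted)
  t <- as.matrix(truth)
  if (!identical(dim(p), dim(t)) || ncol(p) != 3L || nrow(p) < 1L) {
    abort("`predicted` and `truth` must be n x 3 with equal n >= 1",
          class = "fetaltrack_argument_error")
  }
  ok <- stats::complete.cases(p) & stats::complete.cases(t)
  sq <- (p[ok, , drop = FALSE] - t[ok, , drop = FALSE])^2
  tibble(
    axis = c("x", "y", "z"),
    n = sum(ok),
    mse = colMeans(sq),
    mse_sd = apply(sq, 2, function(v) if (length(v) < 2) 0 else sd(v)),
    rmse = sqrt(colMeans(sq))
  )
}

#' Grouped mean ± sd summaries of localization metrics
#'
#' Summarizes per-run Dice and IoU records by grouping labels — echo-time
#' index, gestational-age class, fetal presentation, or any other columns
#' present — in the shape of a per-group performance table: mean and sd of
#' each metric plus the group size. Groups are the observed combinations;
#' a grouping level with no records is omitted with a warning (when the
#' column is a factor carrying the level).
#'
#' @param records tibble/data frame with numeric `dsc` and `iou` columns
#'   and the grouping columns.
#' @param by character vector of grouping column names.
#' @return A tibble with one row per group: `n`, `dsc_mean`, `dsc_sd`,
#'   `iou_mean`, `iou_sd`.
#' @export
summarize_groups <- function(records, by) {
  records <- as_tibble(records)
  missing_cols <- setdiff(c(by, "dsc", "iou"), names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("unknown column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "fetaltrack_argument_error")
  }
  if (nrow(records) == 0) {
    abort("`records` must be non-empty", class = "fetaltrack_argument_error")
  }
  for (col in by) {
    if (is.factor(records[[col]])) {
      unused <- setdiff(levels(records[[col]]), unique(as.character(records[[col]])))
      if (length(unused) > 0) {
        warn(sprintf("omitting empty group(s) of `%s`: %s", col,
                     paste(unused, collapse = ", ")))
      }
    }
  }
  sd0 <- function(v) if (length(v) < 2) 0 else sd(v)
  records %>%
    group_by(dplyr::across(dplyr::all_of(by))) %>%
    summarise(n = dplyr::n(),
              dsc_mean = mean(.data$dsc), dsc_sd = sd0(.data$dsc),
              iou_mean = mean(.data$iou), iou_sd = sd0(.data$iou),
              .groups = "drop")
}

#' Default phantom experiment configuration
#'
#' The evaluation protocol the closed loop is benchmarked on: a sphere
#' phantom acquired with 3 mm isotropic voxels and TE 90 ms over 50
#' repetitions, with step translations timed so that the displaced phantom
#' first appears in the images of repetitions 7, 18, 29, 36 and 46 — under
#' two-repetition latency the FOV corrections then land at repetitions 9,
#' 20, 31, 38 and 48. Step sizes are multiples of the 3 mm voxel so the
#' recentering is numerically unambiguous.
#'
#' @param n_repetitions series length.
#' @param edge,spacing_mm,te_ms,noise_sigma,seed acquisition settings.
#' @param radius_mm phantom sphere radius.
#' @param events list of [motion_event()]s.
#' @param latency_repetitions,localizer controller settings.
#' @return A list of configs consumed by [run_phantom_experiment()].
#' @export
phantom_config <- function(n_repetitions = 50L, edge = 64L, spacing_mm = 3.0,
                           te_ms = 90, noise_sigma = 0, seed = 1L,
                           radius_mm = 45,
                           events = list(
                             motion_event(7, c(9, 0, 0)),
                             motion_event(18, c(-6, 0, 0)),
                             motion_event(29, c(0, 9, 0)),
                             motion_event(36, c(0, 0, 6)),
                             motion_event(46, c(0, -9, 0))
                           ),
                           latency_repetitions = 2L,
                           localizer = "intensity") {
  if (missing(events)) {
    # default events are laid out for the full 50-repetition protocol;
    # trim them for shorter series
    events <- Filter(function(e) e$first_visible_repetition <= n_repetitions,
                     events)
  }
  list(scene = make_sphere_world(radius_mm = radius_mm),
       trajectory = step_trajectory(events, n_repetitions),
       acq = acquisition_config(edge = edge, spacing_mm = spacing_mm,
                                te_ms = te_ms, n_repetitions = n_repetitions,
                                noise_sigma = noise_sigma, seed = seed),
       loop = loop_config(latency_repetitions = latency_repetitions,
                          localizer = localizer))
}

#' Run and score the phantom tracking experiment
#'
#' Executes [run_closed_loop()] on a sphere-phantom configuration and
#' scores it per the phantom evaluation protocol: a latency table mapping
#' each motion event to the repetition of the resulting FOV correction,
#' and the image-frame CoM residuals of all corrected repetitions against
#' the image-frame CoM of the first repetition (pass: within one voxel).
#'
#' @param config from [phantom_config()].
#' @return A `phantom_report`: list with `records` (the `tracking_run`),
#'   `latency` (tibble: event_rep, correction_rep, latency), `residuals`
#'   (tibble: repetition, offset per axis in voxels vs repetition 1) and
#'   `passes` (named logicals).
#' @export
run_phantom_experiment <- function(config = phantom_config()) {
  run <- run_closed_loop(config$scene, config$trajectory, config$acq,
                         config$loop)
  shift_reps <- run$repetition[abs(run$shift_x) + abs(run$shift_y) +
                                 abs(run$shift_z) > 0]
  event_reps <- vapply(config$trajectory$events,
                       function(e) e$first_visible_repetition, integer(1))
  latency <- tibble(
    event_rep = event_reps,
    correction_rep = vapply(event_reps, function(r) {
      later <- shift_reps[shift_reps > r]
      if (length(later) == 0) NA_integer_ else min(later)
    }, integer(1))
  ) %>% mutate(latency = .data$correction_rep - .data$event_rep)
  spacing <- config$acq$spacing_mm
  ref <- unlist(run[1, c("resid_x", "resid_y", "resid_z")], use.names = FALSE)
  corrected <- run %>%
    filter(abs(.data$shift_x) + abs(.data$shift_y) + abs(.data$shift_z) > 0)
  residuals <- tibble(
    repetition = corrected$repetition,
    dvox_x = (corrected$resid_x - ref[1]) / spacing,
    dvox_y = (corrected$resid_y - ref[2]) / spacing,
    dvox_z = (corrected$resid_z - ref[3]) / spacing
  )
  expected_latency <- config$loop$latency_repetitions
  passes <- c(
    all_events_corrected = !anyNA(latency$correction_rep),
    latency_exact = !anyNA(latency$correction_rep) &&
      all(latency$latency == expected_latency),
    one_shift_per_event = length(shift_reps) == length(event_reps),
    residuals_within_one_voxel = nrow(residuals) > 0 &&
      max(abs(c(residuals$dvox_x, residuals$dvox_y, residuals$dvox_z))) <= 1,
    loop_completed = nrow(run) == config$trajectory$n_repetitions
  )
  structure(list(records = run, latency = latency, residuals = residuals,
                 passes = passes, config = config),
            class = "phantom_report")
}

#' @export
print.phantom_report <- function(x, ...) {
  cat("<phantom_report>\n")
  print(x$latency)
  cat(sprintf("max |residual| at corrected repetitions: %.3f voxel\n",
              if (nrow(x$residuals) > 0) {
                max(abs(c(x$residuals$dvox_x, x$residuals$dvox_y,
                          x$residuals$dvox_z)))
              } else NA_real_))
  status <- ifelse(x$passes, "pass", "FAIL")
  for (nm in names(x$passes)) cat(sprintf("  %-28s %s\n", nm, status[nm]))
  invisible(x)
}

#' @export
tidy.phantom_report <- function(x, ...) x$latency

#' @export
glance.phantom_report <- function(x, ...) {
  tibble(n_events = nrow(x$latency),
         n_corrected = sum(!is.na(x$latency$correction_rep)),
         max_residual_vox = if (nrow(x$residuals) > 0) {
           max(abs(c(x$residuals$dvox_x, x$residuals$dvox_y,
                     x$residuals$dvox_z)))
         } else NA_real_,
         all_pass = all(x$passes))
}
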