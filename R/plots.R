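#' Plot a tracking run
#'
#' Per-axis world CoM of the tracked object and the FOV center over
#' repetitions — the standard view of a prospective-correction run: steps
#' in the CoM trace mark motion, matching steps in the FOV trace two
#' repetitions later mark the applied corrections.
#'
#' @param object a `tracking_run` from [run_closed_loop()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tracking_run <- function(object, ...) {
  rec <- tidy(object)
  long <- rec %>%
    select("repetition", "com_x", "com_y", "com_z",
           "fov_x", "fov_y", "fov_z") %>%
    tidyr::pivot_longer(-"repetition",
                        names_to = c("series", "axis"), names_sep = "_") %>%
    mutate(series = dplyr::recode(.data$series,
                                  com = "object CoM", fov = "FOV center"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$repetition, y = .data$value,
                                     color = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(x = "x (mm)", y = "y (mm)", z = "z (mm)"))) +
    ggplot2::labs(x = "repetition", y = "world coordinate (mm)",
                  color = NULL,
                  title = "Closed-loop tracking: CoM and FOV center") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param object a `localizer_fit` from [train_localizer()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.localizer_fit <- function(object, ...) {
  h <- tidy(object) %>%
    tidyr::pivot_longer(c("train_gdl", "val_dsc"),
                        names_to = "metric", values_to = "value") %>%
    filter(!is.na(.data$value))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(train_gdl = "training GDL",
                            val_dsc = "validation DSC"))) +
    ggplot2::labs(x = "epoch", y = NULL, title = "Localizer training") +
    ggplot2::theme_minimal()
}

#' Plot phantom recentering residuals
#'
#' Image-frame CoM offset (in voxels, relative to repetition 1) at the
#' corrected repetitions; the one-voxel acceptance band is shaded.
#'
#' @param object a `phantom_report` from [run_phantom_experiment()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.phantom_report <- function(object, ...) {
  r <- object$residuals %>%
    tidyr::pivot_longer(-"repetition", names_to = "axis",
                        names_prefix = "dvox_", values_to = "voxels")
  ggplot2::ggplot(r, ggplot2::aes(x = .data$repetition, y = .data$voxels,
                                  color = .data$axis)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = -1, ymax = 1,
                      alpha = 0.1, fill = "grey50") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "corrected repetition",
                  y = "image-frame CoM offset vs repetition 1 (voxels)",
                  title = "Phantom recentering accuracy") +
    ggplot2::theme_minimal()
}
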