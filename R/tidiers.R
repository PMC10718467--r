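#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an encoding fit
#'
#' One row per (voxel, stage, split), matching the `results` tibble of
#' [run_encoding_corrected()].
#'
#' @param x An `encoding_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.encoding_fit <- function(x, ...) {
  tibble::as_tibble(x$results)
}

#' One-row summary of an encoding fit
#'
#' @param x An `encoding_fit`.
#' @param ... Unused.
#' @return A one-row tibble: counts, the reliability floors, and the grand
#'   median corrected explained variance.
#' @export
glance.encoding_fit <- function(x, ...) {
  tibble::tibble(
    n_voxels = length(unique(x$results$voxel)),
    n_stages = x$n_stages,
    n_splits = nrow(x$plan),
    k_meas = x$k_meas,
    k_pred = x$k_pred,
    median_r2_corrected = stats::median(x$results$r2_corrected)
  )
}

#' Tidy a resampling result
#'
#' @param x A `resample_result` (bootstrap or permutation test).
#' @param ... Unused.
#' @return A tibble with one row per resampling draw.
#' @export
tidy.resample_result <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$draws), statistic = x$draws)
}

#' One-row summary of a resampling result
#'
#' @param x A `resample_result`.
#' @param ... Unused.
#' @return A one-row tibble: observed statistic, p-value, tail, resamples.
#' @export
glance.resample_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    observed = x$observed,
    p_value = x$p_value,
    tail = x$tail,
    n_resamples = x$n_resamples
  )
}

#' Plot corrected explained variance by stage
#'
#' Split-median noise-corrected explained variance per voxel, summarized by
#' stage (median across voxels with an interquartile ribbon).
#'
#' @param object An `encoding_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.encoding_fit <- function(object, ...) {
  med <- object$results |>
    dplyr::group_by(.data$voxel, .data$stage) |>
    dplyr::summarise(r2 = stats::median(.data$r2_corrected), .groups = "drop")
  by_stage <- med |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      mid = stats::median(.data$r2),
      lo = stats::quantile(.data$r2, 0.25),
      hi = stats::quantile(.data$r2, 0.75),
      .groups = "drop"
    )
  ggplot2::ggplot(by_stage, ggplot2::aes(.data$stage, .data$mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "model stage",
                  y = expression("corrected" ~ R^2 ~ "(median over splits)"))
}

#' Plot ROI best-stage positions
#'
#' Mean minmax-normalized best-stage position per ROI with SEM error bars,
#' from [roi_best_stage()] or the `summary` element of
#' [roi_best_stage_rsa()].
#'
#' @param roi_summary Tibble with columns roi, mean_position, sem.
#' @return A ggplot.
#' @export
plot_roi_positions <- function(roi_summary) {
  ggplot2::ggplot(
    roi_summary,
    ggplot2::aes(.data$roi, .data$mean_position)
  ) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_position - .data$sem,
                   ymax = .data$mean_position + .data$sem),
      width = 0.2
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "ROI", y = "best-stage position")
}

#' Plot per-component stage-selection results
#'
#' Mean evaluated explained variance per component with SEM over iterations,
#' from [summarize_stage_selection()].
#'
#' @param selection_summary Tibble with columns target, mean_r2, sem_r2.
#' @return A ggplot.
#' @export
plot_component_r2 <- function(selection_summary) {
  ggplot2::ggplot(
    selection_summary,
    ggplot2::aes(.data$target, .data$mean_r2)
  ) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_r2 - .data$sem_r2,
                   ymax = .data$mean_r2 + .data$sem_r2),
      width = 0.2
    ) +
    ggplot2::labs(x = "component", y = expression("evaluated" ~ r^2)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
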