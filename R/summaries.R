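#' Minmax-normalized stage position
#'
#' Assigns each model stage a relative depth in [0, 1]: the first stage maps
#' to 0 and the last to 1, linearly in stage order. Single-stage models map
#' to 0 by convention (with a warning).
#'
#' @param stage_index Stage index (1-based).
#' @param n_stages Number of stages in the model.
#' @return Position in [0, 1].
#' @export
stage_position <- function(stage_index, n_stages) {
  if (any(stage_index < 1 | stage_index > n_stages)) {
    stop("stage_index out of range", call. = FALSE)
  }
  if (n_stages < 2) {
    warning("single-stage model: position fixed at 0")
    return(rep(0, length(stage_index)))
  }
  (stage_index - 1) / (n_stages - 1)
}

#' Per-voxel best-stage map
#'
#' For each voxel, the stage with the maximal split-median explained variance
#' (argmax; ties broken toward the lowest stage) and its minmax-normalized
#' position. Voxels whose explained variance is zero at every stage are
#' flagged and excluded from downstream medians.
#'
#' @param medians Tibble with columns target (voxel id), stage, and a
#'   median-r2 column.
#' @param n_stages Number of stages (defaults to the max stage present).
#' @param value Name of the median-r2 column.
#' @return Tibble: voxel, best_stage, position, excluded.
#' @export
best_stage_map <- function(medians, n_stages = max(medians$stage),
                           value = setdiff(names(medians), c("target", "stage", "n_splits"))[1]) {
  medians |>
    dplyr::group_by(voxel = .data$target) |>
    dplyr::arrange(.data$stage, .by_group = TRUE) |>
    dplyr::summarise(
      best_stage = .data$stage[which.max(.data[[value]])],
      excluded = all(.data[[value]] == 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      position = stage_position(.data$best_stage, n_stages)
    )
}

#' Across-model consensus best-stage map
#'
#' Median of the per-voxel best-stage positions across a list of models.
#'
#' @param maps List of [best_stage_map()] tibbles over the same voxels.
#' @return Tibble: voxel, median_position.
#' @export
best_stage_map_consensus <- function(maps) {
  dplyr::bind_rows(maps, .id = "model") |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$voxel) |>
    dplyr::summarise(median_position = stats::median(.data$position), .groups = "drop")
}

#' ROI-aggregated best-stage position
#'
#' Median best-stage position across voxels within each ROI for each
#' participant, followed by the mean across participants (with
#' across-participant SEM). Participants with no usable voxels in an ROI are
#' skipped with a warning; ROIs empty overall are omitted.
#'
#' @param map A [best_stage_map()] tibble.
#' @param voxel_meta Tibble with columns voxel, participant, roi.
#' @return Tibble: roi, mean_position, sem, n_participants.
#' @export
roi_best_stage <- function(map, voxel_meta) {
  df <- dplyr::inner_join(map, voxel_meta, by = "voxel") |>
    dplyr::filter(!.data$excluded, .data$roi != "none")
  per_part <- df |>
    dplyr::group_by(.data$roi, .data$participant) |>
    dplyr::summarise(median_position = stats::median(.data$position), .groups = "drop")
  all_parts <- unique(voxel_meta$participant)
  missing <- setdiff(
    paste(rep(unique(df$roi), each = length(all_parts)), all_parts),
    paste(per_part$roi, per_part$participant)
  )
  if (length(missing) > 0) {
    warning(sprintf("%d participant/ROI cell(s) had no usable voxels and were skipped",
                    length(missing)))
  }
  per_part |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      mean_position = mean(.data$median_position),
      sem = stats::sd(.data$median_position) / sqrt(dplyr::n()),
      n_participants = dplyr::n(),
      .groups = "drop"
    )
}

#' Effective dimensionality (participation ratio)
#'
#' `ED = (sum lambda_i)^2 / sum lambda_i^2`, where lambda_i are the
#' eigenvalues of the feature covariance (the squared singular values of the
#' preprocessed matrix). Preprocessing matches the model-brain comparison the
#' measure accompanies: `"demean"` (regression-style) or `"zscore"`
#' (RSA-style; zero-variance features dropped with a warning).
#'
#' @param feature_matrix Samples-by-features matrix (>= 2 samples).
#' @param preprocessing `"demean"` or `"zscore"`.
#' @return The effective dimensionality; an all-zero matrix returns 0 with a
#'   `"degenerate"` attribute.
#' @export
effective_dim <- function(feature_matrix, preprocessing = c("demean", "zscore")) {
  preprocessing <- match.arg(preprocessing)
  stopifnot(is.matrix(feature_matrix), nrow(feature_matrix) >= 2)
  X <- switch(preprocessing,
    demean = scale(feature_matrix, center = TRUE, scale = FALSE),
    zscore = {
      sds <- apply(feature_matrix, 2, stats::sd)
      if (any(sds == 0)) {
        warning(sprintf("%d zero-variance feature(s) dropped", sum(sds == 0)))
        feature_matrix <- feature_matrix[, sds > 0, drop = FALSE]
      }
      if (ncol(feature_matrix) == 0) {
        matrix(0, nrow(feature_matrix), 0)
      } else {
        scale(feature_matrix)
      }
    }
  )
  if (ncol(X) == 0 || all(X == 0)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  lam <- svd(X, nu = 0, nv = 0)$d^2
  sum(lam)^2 / sum(lam^2)
}
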