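#' Predict component responses
#'
#' Predicts the six cortical response components with the same ridge /
#' leave-one-out / split machinery as the voxelwise encoding, but with no
#' noise-ceiling correction: component predictions are reported as raw
#' explained variance (squared clamped Pearson correlation).
#'
#' @param activations Named list of stage activation matrices.
#' @param components Sounds-by-6 component response matrix (labeled columns),
#'   or the list returned by [generate_components()].
#' @param plan A [make_split_plan()].
#' @param grid Regularization grid.
#' @return A tibble, one row per (component, stage, split), with r, r2,
#'   lambda and flags (see [run_encoding()]); the `target` column holds the
#'   component label.
#' @export
predict_components <- function(activations, components, plan,
                               grid = lambda_grid()) {
  if (is.list(components) && !is.matrix(components)) {
    components <- components$responses
  }
  if (ncol(components) != 6) {
    stop("components must have exactly 6 columns", call. = FALSE)
  }
  run_encoding(activations, components, plan, grid)
}

#' Split-based best-stage selection
#'
#' The 5-select / 5-evaluate protocol for comparing models by their
#' best-predicting stage: in each iteration, the cross-validation splits are
#' randomly partitioned into a selection half and an evaluation half; the
#' stage maximizing the median r^2 over the selection splits is chosen (ties
#' to the lowest stage index), and the median r^2 of that stage over the
#' evaluation splits is reported. Iterations are aggregated with
#' [summarize_stage_selection()] (mean and SEM over iterations).
#'
#' @param records Encoding results tibble with columns target, stage, split,
#'   r2 (from [run_encoding()] / [predict_components()]).
#' @param n_select,n_eval Number of splits used for selection / evaluation.
#' @param n_iter Number of random select/evaluate partitions.
#' @param seed Seed for the partitions.
#' @return Tibble, one row per (target, iteration): `stage_selected` and
#'   `r2_eval`.
#' @export
best_stage_split_selection <- function(records, n_select = 5, n_eval = 5,
                                       n_iter = 10, seed = 1) {
  splits <- sort(unique(records$split))
  if (length(splits) != n_select + n_eval) {
    stop("records must contain exactly n_select + n_eval splits", call. = FALSE)
  }
  targets <- unique(records$target)
  with_seed(substream_seed(seed, "stage_selection"), {
    out <- purrr::map(seq_len(n_iter), function(it) {
      sel <- sort(sample(splits, n_select))
      ev <- setdiff(splits, sel)
      purrr::map(targets, function(tg) {
        rec <- records[records$target == tg, ]
        sel_med <- rec[rec$split %in% sel, ] |>
          dplyr::group_by(.data$stage) |>
          dplyr::summarise(m = stats::median(.data$r2), .groups = "drop") |>
          dplyr::arrange(.data$stage)
        best <- sel_med$stage[which.max(sel_med$m)] # ties -> lowest stage
        ev_r2 <- rec$r2[rec$split %in% ev & rec$stage == best]
        tibble::tibble(
          target = tg, iteration = it,
          stage_selected = best, r2_eval = stats::median(ev_r2)
        )
      }) |> dplyr::bind_rows()
    })
  })
  dplyr::bind_rows(out)
}

#' Aggregate stage-selection iterations
#'
#' @param iterations Output of [best_stage_split_selection()].
#' @return Tibble per target: mean and SEM (over iterations) of the evaluated
#'   r^2 and the modal selected stage.
#' @export
summarize_stage_selection <- function(iterations) {
  iterations |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      mean_r2 = mean(.data$r2_eval),
      sem_r2 = stats::sd(.data$r2_eval) / sqrt(dplyr::n()),
      modal_stage = as.integer(names(which.max(table(.data$stage_selected)))),
      n_iter = dplyr::n(),
      .groups = "drop"
    )
}

#' Participant-aggregated best-stage explained variance
#'
#' Voxel-level analogue of the split-based stage selection: applies
#' [best_stage_split_selection()] to per-voxel encoding results, takes for
#' each voxel the mean over iterations, then the median across voxels within
#' each participant, then the mean across participants.
#'
#' @param records Per-voxel encoding results tibble (column `target` =
#'   voxel id) with an r2 column (use `r2_corrected` via `value`).
#' @param participants Named or positional mapping from voxel id to
#'   participant (character vector aligned with the voxel ids).
#' @param value Which column to treat as r2.
#' @param ... Passed to [best_stage_split_selection()].
#' @return List with `per_voxel`, `per_participant`, and the scalar
#'   `aggregate`.
#' @export
aggregate_best_stage_r2 <- function(records, participants, value = "r2", ...) {
  records$r2 <- records[[value]]
  iters <- best_stage_split_selection(records, ...)
  per_voxel <- iters |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(r2 = mean(.data$r2_eval), .groups = "drop")
  vox_ids <- unique(records$target)
  part <- participants[match(per_voxel$target, vox_ids)]
  per_voxel$participant <- part
  per_participant <- per_voxel |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(median_r2 = stats::median(.data$r2), .groups = "drop")
  list(
    per_voxel = per_voxel,
    per_participant = per_participant,
    aggregate = mean(per_participant$median_r2)
  )
}
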