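#' Representational dissimilarity matrix
#'
#' Computes the RDM of a response matrix: features (voxels or model units)
#' are z-scored across sounds, and entry (i, j) is 1 minus the Pearson
#' correlation between the responses of sounds i and j across features.
#' Zero-variance features are dropped with a warning; a zero-variance sound
#' row yields flagged `NA` entries.
#'
#' @param response_matrix Sounds-by-features matrix (>= 3 sounds,
#'   >= 2 features).
#' @param source Optional source tag (e.g. participant/ROI or model stage).
#' @return A symmetric sounds-by-sounds matrix of class `rdm` with zero
#'   diagonal, entries in [0, 2].
#' @export
compute_rdm <- function(response_matrix, source = NULL) {
  stopifnot(is.matrix(response_matrix))
  if (nrow(response_matrix) < 3 || ncol(response_matrix) < 2) {
    stop("need >= 3 sounds and >= 2 features", call. = FALSE)
  }
  sds <- apply(response_matrix, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance feature(s) dropped", sum(sds == 0)))
    response_matrix <- response_matrix[, sds > 0, drop = FALSE]
    if (ncol(response_matrix) < 2) stop("fewer than 2 usable features", call. = FALSE)
    sds <- sds[sds > 0]
  }
  z <- scale(response_matrix)
  r <- suppressWarnings(stats::cor(t(z)))
  rdm <- 1 - r
  diag(rdm) <- 0
  flagged <- anyNA(rdm)
  structure(rdm, source = source, flagged_na = flagged,
            class = c("rdm", class(rdm)))
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d sounds", nrow(x)))
  if (!is.null(attr(x, "source"))) cat(sprintf(" (%s)", attr(x, "source")))
  cat("\n")
  invisible(x)
}

upper_tri_values <- function(rdm) rdm[upper.tri(rdm)]

#' Spearman similarity of two RDMs
#'
#' Spearman rank correlation between the strict upper triangles of two RDMs
#' over the same sounds in the same order. A constant RDM makes the rank
#' correlation undefined; 0 is returned with a `"degenerate"` attribute.
#'
#' @param rdm_a,rdm_b Square dissimilarity matrices of equal size.
#' @return Spearman rho.
#' @export
rdm_similarity <- function(rdm_a, rdm_b) {
  stopifnot(all(dim(rdm_a) == dim(rdm_b)))
  a <- upper_tri_values(rdm_a)
  b <- upper_tri_values(rdm_b)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  stats::cor(a, b, method = "spearman")
}

split_by_participant <- function(responses, participants) {
  v123 <- if (inherits(responses, "voxel_tensor")) {
    if (missing(participants) || is.null(participants)) {
      participants <- responses$participant
    }
    scan_average(responses)
  } else {
    responses
  }
  lapply(split(seq_along(participants), participants), function(idx) {
    v123[, idx, drop = FALSE]
  })
}

#' Split-based best-stage RSA
#'
#' For each participant and each train/test split: computes the model-stage
#' and participant RDMs over the training sounds, selects the stage with the
#' highest Spearman rho to the participant RDM, recomputes both RDMs on the
#' test sounds, and records the test rho. The per-participant value is the
#' median over splits; the model-level summary is the mean across
#' participants.
#'
#' @param activations Named list of stage activation matrices.
#' @param responses `voxel_tensor` or sounds-by-voxels matrix.
#' @param plan A [make_split_plan()].
#' @param participants Participant label per voxel (taken from the
#'   `voxel_tensor` when omitted).
#' @return List with `per_split` tibble (participant, split, stage_selected,
#'   rho_test), `per_participant` (median rho), and scalar `model_rho`.
#' @export
best_stage_rsa <- function(activations, responses, plan, participants = NULL) {
  by_part <- split_by_participant(responses, participants)
  n_stages <- length(activations)
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    tr <- plan$train[[i]]
    te <- plan$test[[i]]
    model_tr <- lapply(activations, function(a) compute_rdm(a[tr, , drop = FALSE]))
    model_te <- lapply(activations, function(a) compute_rdm(a[te, , drop = FALSE]))
    for (p in names(by_part)) {
      brain_tr <- compute_rdm(by_part[[p]][tr, , drop = FALSE], source = p)
      rhos <- vapply(model_tr, function(m) as.numeric(rdm_similarity(m, brain_tr)), numeric(1))
      best <- which.max(rhos) # which.max breaks ties toward the lowest stage
      brain_te <- compute_rdm(by_part[[p]][te, , drop = FALSE], source = p)
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant = p, split = plan$split[i],
        stage_selected = as.integer(best),
        rho_test = as.numeric(rdm_similarity(model_te[[best]], brain_te))
      )
    }
  }
  per_split <- dplyr::bind_rows(rows)
  per_participant <- per_split |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(rho_median = stats::median(.data$rho_test), .groups = "drop")
  list(
    per_split = per_split,
    per_participant = per_participant,
    model_rho = mean(per_participant$rho_median)
  )
}

#' Leave-one-participant-out RSA noise ceiling
#'
#' For each held-out participant and each split, the Spearman rho between the
#' held-out participant's test-sound RDM and the element-wise mean of the
#' other participants' test-sound RDMs; the per-participant value is the
#' median over splits, and the ceiling is the mean across held-out
#' participants (the "lower bound" of the noise ceiling).
#'
#' @param responses `voxel_tensor` or sounds-by-voxels matrix.
#' @param plan A [make_split_plan()].
#' @param participants Participant label per voxel.
#' @return List with `per_participant` tibble and scalar `ceiling`.
#' @export
noise_ceiling <- function(responses, plan, participants = NULL) {
  by_part <- split_by_participant(responses, participants)
  if (length(by_part) < 3) stop("need >= 3 participants", call. = FALSE)
  parts <- names(by_part)
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    te <- plan$test[[i]]
    rdms <- lapply(by_part, function(m) compute_rdm(m[te, , drop = FALSE]))
    for (p in parts) {
      others <- rdms[setdiff(parts, p)]
      mean_rdm <- Reduce(`+`, others) / length(others)
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant = p, split = plan$split[i],
        rho = as.numeric(rdm_similarity(rdms[[p]], mean_rdm))
      )
    }
  }
  per_split <- dplyr::bind_rows(rows)
  per_participant <- per_split |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(rho_median = stats::median(.data$rho), .groups = "drop")
  list(
    per_split = per_split,
    per_participant = per_participant,
    ceiling = mean(per_participant$rho_median)
  )
}

#' ROI-level best-stage RSA
#'
#' Computes, on the full sound set, each participant's fMRI RDM within each
#' ROI and the RDM of every model stage, and records the stage with the
#' maximal Spearman rho (argmax; ties to the lowest stage) together with its
#' minmax-normalized stage position. The summary is the mean position across
#' participants per ROI.
#'
#' @param activations Named list of stage activation matrices.
#' @param responses `voxel_tensor` or sounds-by-voxels matrix.
#' @param participants Participant label per voxel.
#' @param roi_labels ROI label per voxel ("none" voxels are ignored).
#' @return List with `per_participant` tibble (roi, participant, best_stage,
#'   position) and `summary` (roi, mean_position, sem, n_participants).
#' @export
roi_best_stage_rsa <- function(activations, responses, participants = NULL,
                               roi_labels = NULL) {
  if (inherits(responses, "voxel_tensor")) {
    if (is.null(roi_labels)) roi_labels <- responses$roi
    if (is.null(participants)) participants <- responses$participant
    responses <- scan_average(responses)
  }
  n_stages <- length(activations)
  model_rdms <- lapply(activations, compute_rdm)
  rois <- setdiff(unique(roi_labels), "none")
  rows <- list()
  for (roi in rois) {
    for (p in unique(participants)) {
      idx <- which(roi_labels == roi & participants == p)
      if (length(idx) < 2) next
      brain <- compute_rdm(responses[, idx, drop = FALSE],
                           source = paste(p, roi, sep = "/"))
      rhos <- vapply(model_rdms, function(m) {
        as.numeric(rdm_similarity(m, brain))
      }, numeric(1))
      best <- which.max(rhos)
      rows[[length(rows) + 1]] <- tibble::tibble(
        roi = roi, participant = p,
        best_stage = as.integer(best),
        position = stage_position(best, n_stages)
      )
    }
  }
  per_participant <- dplyr::bind_rows(rows)
  summary <- per_participant |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      mean_position = mean(.data$position),
      sem = stats::sd(.data$position) / sqrt(dplyr::n()),
      n_participants = dplyr::n(),
      .groups = "drop"
    )
  list(per_participant = per_participant, summary = summary)
}

#' Plot an RDM
#'
#' @param object An `rdm`.
#' @param ... Unused.
#' @return A ggplot heatmap.
#' @exportS3Method ggplot2::autoplot
autoplot.rdm <- function(object, ...) {
  n <- nrow(object)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$dissimilarity <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$dissimilarity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 2), name = "1 - r") +
    ggplot2::labs(x = "sound", y = "sound")
}
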