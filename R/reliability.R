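#' Spearman--Brown prophecy correction
#'
#' Predicts the reliability of a measurement lengthened by `factor` from the
#' reliability `r` of the shorter measurement:
#' `r_sb = factor * r / (1 + (factor - 1) * r)`. Used with `factor = 3` to
#' estimate the reliability of the 3-scan average from single-scan-pair
#' correlations.
#'
#' @param r Reliability (correlation) of the shorter measurement.
#' @param factor Lengthening factor (>= 1).
#' @return Corrected reliability; the singular point `r = -1/(factor-1)` is
#'   returned as `NaN` with a `"singular"` attribute.
#' @export
spearman_brown <- function(r, factor = 3) {
  stopifnot(factor >= 1)
  denom <- 1 + (factor - 1) * r
  out <- factor * r / denom
  if (any(denom == 0)) {
    out[denom == 0] <- NaN
    attr(out, "singular") <- TRUE
  }
  out
}

# median of the three pairwise scan correlations for each column of a
# sounds x targets x 3 array (or list of three sounds x targets matrices)
median_pairwise_cor <- function(mats) {
  pairs <- list(c(1, 2), c(2, 3), c(1, 3))
  n_targets <- ncol(mats[[1]])
  vapply(seq_len(n_targets), function(v) {
    rs <- vapply(pairs, function(p) {
      as.numeric(safe_cor(mats[[p[1]]][, v], mats[[p[2]]][, v]))
    }, numeric(1))
    stats::median(rs)
  }, numeric(1))
}

#' Measured-response reliability per voxel
#'
#' The reliability of the measured voxel response: the median of the Pearson
#' correlations between all 3 pairs of scans (1-2, 2-3, 1-3), computed over
#' the supplied sounds, then Spearman--Brown corrected for the tripling of
#' data in the 3-scan average. Zero-variance scan vectors give pairwise
#' correlations of 0 (flagged behavior of [safe_cor()]).
#'
#' @param responses Sounds x voxels x 3 array, or a `voxel_tensor`.
#' @param sounds Optional sound indices to restrict to (e.g. the 83 training
#'   sounds of a split).
#' @return Numeric vector of per-voxel reliabilities.
#' @export
measured_reliability <- function(responses, sounds = NULL) {
  if (inherits(responses, "voxel_tensor")) responses <- responses$responses
  stopifnot(length(dim(responses)) == 3, dim(responses)[3] == 3)
  if (is.null(sounds)) sounds <- seq_len(dim(responses)[1])
  mats <- lapply(1:3, function(k) {
    array(responses[sounds, , k], dim = c(length(sounds), dim(responses)[2]))
  })
  spearman_brown(median_pairwise_cor(mats), 3)
}

#' Predicted-response reliability per voxel
#'
#' The reliability of the predicted voxel response: the median of the
#' correlations between all pairs of predicted test responses from models
#' fitted separately to each single scan, Spearman--Brown corrected.
#'
#' @param predictions List of three sounds-by-voxels prediction matrices
#'   (one per scan-specific fit).
#' @return Numeric vector of per-voxel reliabilities.
#' @export
prediction_reliability <- function(predictions) {
  stopifnot(length(predictions) == 3)
  spearman_brown(median_pairwise_cor(predictions), 3)
}

#' Critical Pearson correlation (reliability floor)
#'
#' The one-sided p < alpha significance threshold for the correlation of two
#' n-dimensional Gaussian variables, `r = t / sqrt(t^2 + df)` with
#' `t = qt(1 - alpha, df)`, `df = n - 2`. Used as the floor k applied to the
#' measured- and predicted-response reliabilities in the attenuation
#' correction (0.182 for n = 83 and 0.183 for n = 82, to 3 decimals).
#'
#' @param n Sample size (>= 4).
#' @param alpha Significance level.
#' @return The critical correlation.
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (any(n < 4)) stop("n must be >= 4", call. = FALSE)
  df <- n - 2
  t <- stats::qt(1 - alpha, df)
  t / sqrt(t^2 + df)
}

#' Noise-corrected explained variance
#'
#' The correction for attenuation: divides the raw test-set r^2 by the
#' product of the measured- and predicted-response reliabilities, each
#' floored at its critical value k, and clips the result at 1.
#'
#' @param r_test Clamped test-set Pearson correlation(s).
#' @param r_meas Measured-response reliability (Spearman--Brown corrected).
#' @param r_pred Predicted-response reliability (Spearman--Brown corrected).
#' @param k_meas,k_pred Reliability floors (defaults: critical r for the 83
#'   training and 82 testing sounds).
#' @return Corrected R^2 in [0, 1].
#' @export
corrected_r2 <- function(r_test, r_meas, r_pred,
                         k_meas = critical_r(83), k_pred = critical_r(82)) {
  out <- r_test^2 / (pmax(r_meas, k_meas) * pmax(r_pred, k_pred))
  pmin(out, 1)
}

#' Projection-based voxel-selection reliability
#'
#' The modified reliability measure used to screen voxels:
#' `r = 1 - ||v12 - proj_v3 v12|| / ||v12||`, where `proj_v3 v12` is the
#' projection of the scan-1/2 average response onto the scan-3 response.
#' Bounded in [0, 1]; unlike a correlation it assigns high values to voxels
#' with a consistent response even when the response varies little across
#' sounds. The squared-magnitude variant is available via `squared = TRUE`.
#'
#' @param v12 Response vector averaged over scans 1-2.
#' @param v3 Scan-3 response vector.
#' @param squared Use squared magnitudes in numerator and denominator.
#' @return Reliability in [0, 1]; a zero `v12` returns 0 with a
#'   `"degenerate"` attribute.
#' @export
selection_reliability <- function(v12, v3, squared = FALSE) {
  n12 <- sqrt(sum(v12^2))
  if (n12 == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  n3sq <- sum(v3^2)
  proj <- if (n3sq == 0) rep(0, length(v12)) else (sum(v3 * v12) / n3sq) * v3
  resid <- sqrt(sum((v12 - proj)^2))
  if (squared) 1 - resid^2 / n12^2 else 1 - resid / n12
}

#' Screen voxels by reliability (and optional sound responsiveness)
#'
#' Computes the projection-based selection reliability for every voxel
#' (scan-1/2 average vs scan 3) and keeps voxels at or above the threshold.
#' If per-voxel silence-baseline values are supplied, a sound-responsiveness
#' screen (one-sample t test of the 3-scan mean response against the
#' baseline, p < 0.001 uncorrected) is applied as well; otherwise that screen
#' is skipped with a message.
#'
#' @param responses Sounds x voxels x 3 array or `voxel_tensor`.
#' @param threshold Reliability inclusion threshold.
#' @param baseline Optional numeric vector of per-voxel silence baselines.
#' @param p_cutoff Significance cutoff for the responsiveness t test.
#' @param squared Passed to [selection_reliability()].
#' @return Tibble with columns voxel, reliability, responsive, pass.
#' @export
screen_voxels <- function(responses, threshold = 0.3, baseline = NULL,
                          p_cutoff = 0.001, squared = FALSE) {
  if (inherits(responses, "voxel_tensor")) responses <- responses$responses
  n_vox <- dim(responses)[2]
  v12 <- apply(responses[, , 1:2, drop = FALSE], c(1, 2), mean)
  v3 <- array(responses[, , 3], dim = dim(responses)[1:2])
  rel <- vapply(seq_len(n_vox), function(v) {
    as.numeric(selection_reliability(v12[, v], v3[, v], squared = squared))
  }, numeric(1))
  if (is.null(baseline)) {
    message("no silence baseline supplied; sound-responsiveness screen skipped")
    responsive <- rep(TRUE, n_vox)
  } else {
    v123 <- apply(responses, c(1, 2), mean)
    responsive <- vapply(seq_len(n_vox), function(v) {
      x <- v123[, v]
      if (stats::sd(x) == 0) return(FALSE)
      stats::t.test(x, mu = baseline[v], alternative = "greater")$p.value < p_cutoff
    }, logical(1))
  }
  tibble::tibble(
    voxel = seq_len(n_vox),
    reliability = rel,
    responsive = responsive,
    pass = rel >= threshold & responsive
  )
}

#' Noise-ceiling-corrected voxelwise encoding
#'
#' The full voxelwise modeling procedure with the correction for
#' attenuation. For every stage and split: (1) fit the ridge model (with
#' leave-one-out lambda selection) to the 3-scan-average training responses
#' and correlate predicted with observed test responses (clamped); (2)
#' estimate the measured-response reliability from the 3 scans over the
#' training sounds; (3) refit the model separately on each single scan's
#' training responses and estimate the predicted-response reliability from
#' the 3 test-sound prediction vectors; (4) divide the squared test
#' correlation by the floored product of reliabilities and clip at 1.
#'
#' @param activations Named list of stage activation matrices.
#' @param responses A `voxel_tensor` (or sounds x voxels x 3 array).
#' @param plan A [make_split_plan()].
#' @param grid Regularization grid.
#' @param k_meas,k_pred Reliability floors; defaults are the critical r for
#'   the split's train and test sizes.
#' @return An object of class `encoding_fit`: list with `results` (tibble,
#'   one row per voxel/stage/split: r_test, r2_raw, r_meas, r_pred,
#'   r2_corrected, lambda, flags), the plan, and the floors. Use
#'   [generics::tidy()] / [generics::glance()] / [ggplot2::autoplot()].
#' @export
run_encoding_corrected <- function(activations, responses, plan,
                                   grid = lambda_grid(),
                                   k_meas = NULL, k_pred = NULL) {
  if (inherits(responses, "voxel_tensor")) responses <- responses$responses
  stopifnot(length(dim(responses)) == 3, dim(responses)[3] == 3)
  n_vox <- dim(responses)[2]
  n_train <- length(plan$train[[1]])
  n_test <- length(plan$test[[1]])
  if (is.null(k_meas)) k_meas <- critical_r(n_train)
  if (is.null(k_pred)) k_pred <- critical_r(n_test)
  v123 <- apply(responses, c(1, 2), mean)
  stage_names <- names(activations)
  if (is.null(stage_names)) stage_names <- sprintf("stage_%d", seq_along(activations))

  out <- list()
  for (s in seq_along(activations)) {
    X <- activations[[s]]
    for (i in seq_len(nrow(plan))) {
      tr <- plan$train[[i]]
      te <- plan$test[[i]]
      Xtr <- X[tr, , drop = FALSE]
      Xte <- X[te, , drop = FALSE]
      fit <- ridge_loo_engine(Xtr, v123[tr, , drop = FALSE], Xte, grid)
      cl <- dplyr::bind_rows(purrr::map(seq_len(n_vox), function(v) {
        clamp_correlation(fit$pred[, v], v123[te, v])
      }))
      r_meas <- measured_reliability(responses, sounds = tr)
      scan_preds <- lapply(1:3, function(k) {
        ridge_loo_engine(Xtr, responses[tr, , k], Xte, grid)$pred
      })
      r_pred <- prediction_reliability(scan_preds)
      rows <- tibble::tibble(
        voxel = seq_len(n_vox),
        stage = s,
        stage_name = stage_names[s],
        split = plan$split[i],
        r_test = cl$r,
        r_raw = cl$r_raw,
        r2_raw = cl$r^2,
        r_meas = r_meas,
        r_pred = r_pred,
        r2_corrected = corrected_r2(cl$r, r_meas, r_pred, k_meas, k_pred),
        lambda = fit$lambda,
        sd_zero = cl$sd_zero,
        obs_sd_zero = cl$obs_sd_zero,
        clamped_negative = cl$clamped_negative
      )
      out[[length(out) + 1]] <- rows
    }
  }
  structure(
    list(
      results = dplyr::bind_rows(out),
      plan = plan,
      k_meas = k_meas,
      k_pred = k_pred,
      n_stages = length(activations)
    ),
    class = "encoding_fit"
  )
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf(
    "<encoding_fit> %d voxels x %d stages x %d splits (k_meas = %.3f, k_pred = %.3f)\n",
    length(unique(x$results$voxel)), x$n_stages, nrow(x$plan), x$k_meas, x$k_pred
  ))
  invisible(x)
}
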