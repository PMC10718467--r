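#' The ridge regularization grid
#'
#' 100 logarithmically spaced regularization parameter values,
#' 1e-50, 1e-49, ..., 1e48, 1e49.
#'
#' @return Strictly increasing numeric vector of length 100.
#' @export
lambda_grid <- function() 10^seq(-50, 49, length.out = 100)

#' Random train/test split plan
#'
#' Generates the random splits of the sound set into training and testing
#' sounds used by every cross-validated analysis (default: 10 splits of 165
#' sounds into 83 train / 82 test).
#'
#' @param n_sounds Total number of sounds.
#' @param n_splits Number of random splits.
#' @param n_train Training-set size per split.
#' @param seed Seed for the split randomization.
#' @return A tibble of class `split_plan` with columns split, train, test
#'   (list columns of sound indices).
#' @export
make_split_plan <- function(n_sounds = 165, n_splits = 10, n_train = 83,
                            seed = 1) {
  if (n_train >= n_sounds || n_train < 3) {
    stop("need 3 <= n_train < n_sounds", call. = FALSE)
  }
  with_seed(substream_seed(seed, "splits"), {
    rows <- purrr::map(seq_len(n_splits), function(s) {
      tr <- sort(sample.int(n_sounds, n_train))
      tibble::tibble(
        split = s,
        train = list(tr),
        test = list(setdiff(seq_len(n_sounds), tr))
      )
    })
  })
  structure(dplyr::bind_rows(rows),
    n_sounds = n_sounds,
    class = c("split_plan", class(tibble::tibble()))
  )
}

#' Solve the ridge normal equation
#'
#' Computes the coefficients solving `(X'X + n lambda I) w = X'y` via a thin
#' singular value decomposition (no explicit matrix inversion). At
#' `lambda = 0` with a rank-deficient system, the minimum-norm (pseudoinverse)
#' solution is returned and flagged via the `"pseudo_inverse"` attribute.
#'
#' Inputs are used as supplied: demean columns of `X` and `y` with training
#' means before calling (the higher-level fitting functions do this).
#'
#' @param X n-by-d regressor matrix.
#' @param y Response vector of length n (or n-by-T matrix of responses).
#' @param lambda Nonnegative regularization parameter.
#' @param n Sample-size multiplier of lambda in the normal equation
#'   (defaults to `nrow(X)`).
#' @return Weight vector of length d (or d-by-T matrix).
#' @export
ridge_solve <- function(X, y, lambda, n = nrow(X)) {
  stopifnot(lambda >= 0)
  y <- as.matrix(y)
  sv <- svd(X)
  d <- sv$d
  if (lambda == 0) {
    tol <- max(dim(X)) * max(d, 0) * .Machine$double.eps
    shrink <- ifelse(d > tol, 1 / d, 0)
    pinv_used <- any(d <= tol) || length(d) < ncol(X)
  } else {
    shrink <- d / (d^2 + n * lambda)
    pinv_used <- FALSE
  }
  w <- sv$v %*% (shrink * (t(sv$u) %*% y))
  if (ncol(w) == 1) w <- drop(w)
  attr(w, "pseudo_inverse") <- pinv_used
  w
}

# Core fitting engine shared by voxel and component encoding. Demeans columns
# of the train regressors and targets (train-set statistics applied to the
# test set), selects lambda per target by leave-one-out cross-validation on
# the training sounds via the hat-matrix identity e_i / (1 - h_ii), fits on
# the full training set, and predicts the test sounds. Vectorized over target
# columns; the SVD of the train matrix is shared.
ridge_loo_engine <- function(X_train, Y_train, X_test, grid = lambda_grid()) {
  Y_train <- as.matrix(Y_train)
  n <- nrow(X_train)
  n_targets <- ncol(Y_train)

  x_means <- colMeans(X_train)
  Xc <- sweep(X_train, 2, x_means)
  Xt <- sweep(X_test, 2, x_means)
  y_means <- colMeans(Y_train)
  Yc <- sweep(Y_train, 2, y_means)

  sv <- svd(Xc)
  d2 <- sv$d^2
  U <- sv$u
  UtY <- crossprod(U, Yc)
  U2 <- U^2

  degenerate <- apply(Y_train, 2, stats::sd) == 0

  loo_mse <- matrix(Inf, nrow = length(grid), ncol = n_targets)
  for (g in seq_along(grid)) {
    shrink2 <- d2 / (d2 + n * grid[g])
    h <- pmin(as.vector(U2 %*% shrink2), 1)
    resid <- Yc - U %*% (shrink2 * UtY)
    denom <- pmax(1 - h, 1e-12)
    loo_mse[g, ] <- colMeans((resid / denom)^2)
  }
  # argmin with ties broken toward larger lambda (more regularization)
  best <- apply(loo_mse, 2, function(m) {
    mn <- min(m)
    max(which(m <= mn * (1 + 1e-12) | m == mn))
  })
  best[degenerate] <- length(grid)

  pred <- matrix(0, nrow = nrow(X_test), ncol = n_targets)
  weights_by_lambda <- list()
  for (g in sort(unique(best))) {
    idx <- which(best == g)
    shrink <- sv$d / (d2 + n * grid[g])
    W <- sv$v %*% (shrink * UtY[, idx, drop = FALSE])
    pred[, idx] <- Xt %*% W
  }
  list(
    pred = pred, # demeaned-scale predictions of the test sounds
    lambda = grid[best],
    lambda_index = best,
    loo_mse = loo_mse,
    y_means = y_means,
    degenerate = degenerate
  )
}

#' Select the ridge regularization parameter by leave-one-out CV
#'
#' For each value of the regularization grid, computes the mean over training
#' sounds of the leave-one-out squared prediction error, and returns the
#' minimizing value (ties broken toward larger lambda). A zero-variance
#' target is flagged and assigned the largest grid value.
#'
#' @param X n-by-d regressor matrix (raw; demeaned internally).
#' @param y Response vector of length n (>= 3).
#' @param grid Regularization grid (see [lambda_grid()]).
#' @return Selected lambda, with attributes `loo_mse` (per-grid-value mean
#'   LOO error) and `degenerate`.
#' @export
select_lambda <- function(X, y, grid = lambda_grid()) {
  if (nrow(X) < 3) stop("need at least 3 training sounds", call. = FALSE)
  fit <- ridge_loo_engine(X, y, X[0, , drop = FALSE], grid)
  out <- fit$lambda[1]
  attr(out, "loo_mse") <- fit$loo_mse[, 1]
  attr(out, "degenerate") <- fit$degenerate[1]
  out
}

clamp_correlation <- function(pred, obs) {
  sd_pred <- stats::sd(pred)
  sd_obs <- stats::sd(obs)
  sd_zero <- (sd_pred == 0)
  obs_sd_zero <- (sd_obs == 0)
  r_raw <- if (sd_zero || obs_sd_zero) 0 else stats::cor(pred, obs)
  clamped <- (!sd_zero && !obs_sd_zero && r_raw < 0)
  tibble::tibble(
    r = max(r_raw, 0),
    r_raw = r_raw,
    sd_zero = sd_zero,
    obs_sd_zero = obs_sd_zero,
    clamped_negative = clamped
  )
}

#' Fit and evaluate one train/test split
#'
#' Fits the ridge model (with leave-one-out lambda selection) of a single
#' target on the training sounds of one split and evaluates the Pearson
#' correlation between predicted and observed responses on the test sounds.
#' A prediction with exactly zero standard deviation is recorded as r = 0
#' (flagged `sd_zero`); a negative correlation is clamped to 0 (flagged
#' `clamped_negative`); a zero-variance observed test response is also
#' recorded as 0 with its own flag.
#'
#' @param stage_activations Sounds-by-units activation matrix.
#' @param target Response vector over all sounds.
#' @param split One row of a [make_split_plan()] (list with `train`, `test`
#'   index vectors).
#' @param grid Regularization grid.
#' @return One-row tibble: r, r_raw, r2, lambda, flags.
#' @export
fit_predict_split <- function(stage_activations, target, split,
                              grid = lambda_grid()) {
  tr <- split$train[[1]]
  te <- split$test[[1]]
  assert_finite(stage_activations)
  fit <- ridge_loo_engine(
    stage_activations[tr, , drop = FALSE],
    target[tr],
    stage_activations[te, , drop = FALSE],
    grid
  )
  res <- clamp_correlation(fit$pred[, 1], target[te])
  res$r2 <- res$r^2
  res$lambda <- fit$lambda[1]
  res[, c("r", "r_raw", "r2", "lambda", "sd_zero", "obs_sd_zero", "clamped_negative")]
}

#' Run the voxelwise/component encoding analysis
#'
#' Crosses every target (voxel or component column) with every model stage
#' and every train/test split: ridge regression with leave-one-out lambda
#' selection on the training sounds, evaluation by (clamped) Pearson
#' correlation on the test sounds.
#'
#' @param activations Named list of stage activation matrices
#'   (sounds x units).
#' @param targets Sounds-by-targets response matrix (column names become
#'   target ids) or a vector for a single target.
#' @param plan A [make_split_plan()].
#' @param grid Regularization grid.
#' @return A tibble with one row per (target, stage, split): r, r_raw, r2,
#'   lambda, and degeneracy flags.
#' @export
run_encoding <- function(activations, targets, plan, grid = lambda_grid()) {
  targets <- as.matrix(targets)
  if (is.null(colnames(targets))) {
    colnames(targets) <- sprintf("target_%d", seq_len(ncol(targets)))
  }
  stage_names <- names(activations)
  if (is.null(stage_names)) stage_names <- sprintf("stage_%d", seq_along(activations))
  out <- list()
  for (s in seq_along(activations)) {
    X <- activations[[s]]
    for (i in seq_len(nrow(plan))) {
      tr <- plan$train[[i]]
      te <- plan$test[[i]]
      fit <- ridge_loo_engine(
        X[tr, , drop = FALSE], targets[tr, , drop = FALSE],
        X[te, , drop = FALSE], grid
      )
      rows <- purrr::map(seq_len(ncol(targets)), function(j) {
        clamp_correlation(fit$pred[, j], targets[te, j])
      })
      rows <- dplyr::bind_rows(rows)
      rows$target <- colnames(targets)
      rows$stage <- s
      rows$stage_name <- stage_names[s]
      rows$split <- plan$split[i]
      rows$lambda <- fit$lambda
      rows$r2 <- rows$r^2
      out[[length(out) + 1]] <- rows
    }
  }
  dplyr::bind_rows(out)[, c(
    "target", "stage", "stage_name", "split", "r", "r_raw", "r2", "lambda",
    "sd_zero", "obs_sd_zero", "clamped_negative"
  )]
}

#' Median over splits of encoding results
#'
#' @param results A [run_encoding()] (or corrected) result tibble.
#' @param value Column to aggregate (default `r2`).
#' @return Tibble with one row per (target, stage) and the split-median of
#'   the chosen column as `median_<value>`.
#' @export
median_over_splits <- function(results, value = "r2") {
  out <- results |>
    dplyr::group_by(.data$target, .data$stage) |>
    dplyr::summarise(
      median_value = stats::median(.data[[value]]),
      n_splits = dplyr::n(),
      .groups = "drop"
    )
  names(out)[names(out) == "median_value"] <- paste0("median_", value)
  out
}
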