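new_resample_result <- function(observed, draws, p_value, n_resamples, seed,
                                tail, method, flag = NULL) {
  structure(
    list(
      observed = observed, draws = draws, p_value = p_value,
      n_resamples = n_resamples, seed = seed, tail = tail, method = method,
      flag = flag
    ),
    class = "resample_result"
  )
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf(
    "<resample_result: %s> observed = %.4g, p = %.4g (%s-tailed, %d resamples)\n",
    x$method, x$observed, x$p_value, x$tail, x$n_resamples
  ))
  invisible(x)
}

#' Participant bootstrap model comparison
#'
#' Compares one model's across-participant mean to another model's
#' per-participant values by bootstrap: the reference model's participant
#' values are resampled with replacement `n` times and averaged, and the
#' observed mean of the comparison model is located in that bootstrap
#' distribution. With `direction = "hypothesis"` (default) the one-tailed
#' p-value for "B exceeds A" is the fraction of bootstrap means at or above
#' the observed value; `direction = "as-printed"` instead counts bootstrap
#' means below the observed value.
#'
#' @param values_a Per-participant values of the reference model A.
#' @param observed_b Observed across-participant mean of model B.
#' @param n Number of bootstrap draws.
#' @param seed Seed.
#' @param direction `"hypothesis"` or `"as-printed"` (see Details).
#' @return A `resample_result`.
#' @export
bootstrap_model_comparison <- function(values_a, observed_b, n = 10000,
                                       seed = 1,
                                       direction = c("hypothesis", "as-printed")) {
  direction <- match.arg(direction)
  if (length(values_a) < 2) stop("need >= 2 participants", call. = FALSE)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  draws <- with_seed(substream_seed(seed, "bootstrap"), {
    vapply(seq_len(n), function(i) {
      mean(sample(values_a, length(values_a), replace = TRUE))
    }, numeric(1))
  })
  p <- switch(direction,
    "hypothesis" = sum(draws >= observed_b) / n,
    "as-printed" = sum(draws < observed_b) / n
  )
  new_resample_result(observed_b, draws, p, n, seed, "one",
                      method = "participant bootstrap")
}

#' Permutation test for component prediction differences
#'
#' Tests whether model A predicts a component better than model B from the
#' per-iteration explained variance values of the stage-selection procedure.
#' The observed statistic is `mean(A) - mean(B)`; the null distribution is
#' generated by randomly permuting the model assignment of the pooled values;
#' the one-tailed p-value is the fraction of permuted differences at or above
#' the observed difference (optionally with +1 smoothing).
#'
#' @param scores_a,scores_b Per-iteration explained variance values (>= 2
#'   each).
#' @param n Number of permutations.
#' @param seed Seed.
#' @param smoothed Add-one smoothing of the p-value.
#' @return A `resample_result`.
#' @export
permutation_test_components <- function(scores_a, scores_b, n = 10000,
                                        seed = 1, smoothed = FALSE) {
  if (length(scores_a) < 2 || length(scores_b) < 2) {
    stop("need >= 2 values per model", call. = FALSE)
  }
  observed <- mean(scores_a) - mean(scores_b)
  pooled <- c(scores_a, scores_b)
  na <- length(scores_a)
  draws <- with_seed(substream_seed(seed, "permutation"), {
    vapply(seq_len(n), function(i) {
      idx <- sample.int(length(pooled), na)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, numeric(1))
  })
  p <- if (smoothed) {
    (sum(draws >= observed) + 1) / (n + 1)
  } else {
    sum(draws >= observed) / n
  }
  new_resample_result(observed, draws, p, n, seed, "one",
                      method = "label permutation")
}

#' Wilcoxon signed-rank test for paired model/ROI values
#'
#' Paired signed-rank test (exact for small samples without ties, normal
#' approximation otherwise). All-zero differences return p = 1 with a flag.
#'
#' @param values_a,values_b Paired vectors (equal length >= 5).
#' @param tail `"two"`, `"greater"` (A > B) or `"less"`.
#' @return A list with statistic `V`, `p_value`, `tail`, and `flag`.
#' @export
wilcoxon_signed_rank <- function(values_a, values_b,
                                 tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  if (length(values_a) != length(values_b) || length(values_a) < 5) {
    stop("need equal-length paired samples with >= 5 pairs", call. = FALSE)
  }
  if (all(values_a - values_b == 0)) {
    return(list(V = 0, p_value = 1, tail = tail, flag = "all differences zero"))
  }
  alt <- switch(tail, two = "two.sided", greater = "greater", less = "less")
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, paired = TRUE, alternative = alt)
  )
  list(V = unname(ht$statistic), p_value = ht$p.value, tail = tail, flag = NULL)
}

#' Bonferroni adjustment
#'
#' @param p_values Numeric vector of p-values.
#' @param m Number of comparisons (>= 1).
#' @return `pmin(1, p * m)` elementwise.
#' @export
bonferroni <- function(p_values, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pmin(1, p_values * m)
}
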