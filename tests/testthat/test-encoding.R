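test_that("lambda grid matches the printed specification", {
  g <- lambda_grid()
  expect_length(g, 100)
  expect_equal(g[1], 1e-50)
  expect_equal(g[100], 1e49)
  expect_true(all(diff(g) > 0))
})

test_that("split plan: disjoint covering splits of the right size", {
  plan <- make_split_plan(165, 10, 83, seed = 1)
  expect_equal(nrow(plan), 10)
  for (i in 1:10) {
    tr <- plan$train[[i]]
    te <- plan$test[[i]]
    expect_length(tr, 83)
    expect_length(te, 82)
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), 1:165)
  }
  expect_identical(plan, make_split_plan(165, 10, 83, seed = 1))
  expect_error(make_split_plan(10, 2, 10), "n_train")
})

test_that("ridge_solve matches the brute-force normal equation", {
  set.seed(10)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  w <- ridge_solve(X, y, 0.5)
  expect_equal(as.numeric(w), as.numeric(oracle_ridge(X, y, 0.5)),
               tolerance = 1e-8)
})

test_that("ridge_solve: OLS limit and shrinkage limit", {
  set.seed(11)
  X <- matrix(rnorm(25), 5, 5)
  y <- rnorm(5)
  w <- ridge_solve(X, y, 0)
  expect_lt(sqrt(sum((X %*% w - y)^2)), 1e-10)
  norms <- vapply(lambda_grid(), function(l) {
    sqrt(sum(ridge_solve(X, y, l)^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  # rank-deficient lambda = 0 is flagged as pseudo-inverse
  Xr <- matrix(rnorm(12), 3, 4)
  wr <- ridge_solve(Xr, rnorm(3), 0)
  expect_true(attr(wr, "pseudo_inverse"))
})

test_that("LOO error matches brute-force refitting", {
  set.seed(12)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- as.numeric(X %*% rnorm(5) + 0.3 * rnorm(20))
  grid <- c(1e-4, 1e-2, 1, 100)
  lam <- select_lambda(X, y, grid)
  loo <- attr(lam, "loo_mse")
  for (g in seq_along(grid)) {
    expect_equal(loo[g], oracle_loo_mse(X, y, grid[g]), tolerance = 1e-8)
  }
})

test_that("select_lambda: sparse signal picks small lambda, noise picks large", {
  set.seed(13)
  X <- matrix(rnorm(83 * 50), 83, 50)
  y <- as.numeric(X[, 1] - 2 * X[, 2])
  lam <- select_lambda(X, y)
  grid <- lambda_grid()
  expect_lt(lam, grid[50])
  loo <- attr(lam, "loo_mse")
  expect_lt(min(loo), loo[100])

  y_noise <- rnorm(83)
  lam_n <- select_lambda(X, y_noise)
  expect_gte(which(grid == as.numeric(lam_n)), 50)

  lam_d <- select_lambda(X, rep(2, 83))
  expect_equal(as.numeric(lam_d), grid[100])
  expect_true(attr(lam_d, "degenerate"))
})

test_that("fit_predict_split: identifiability and clamping rules", {
  set.seed(14)
  X <- matrix(rnorm(60 * 8), 60, 8)
  plan <- make_split_plan(60, 1, 30, seed = 2)
  split <- plan[1, ]
  y <- as.numeric(X %*% rnorm(8)) + 5
  res <- fit_predict_split(X, y, split)
  expect_gt(res$r, 1 - 1e-6)
  expect_false(res$sd_zero)

  # all-zero regressors give a constant prediction: r = 0, sd-zero flag
  res0 <- fit_predict_split(matrix(0, 60, 3), y, split)
  expect_equal(res0$r, 0)
  expect_true(res0$sd_zero)

  # anti-predictive target: negative raw r clamped to 0
  y_anti <- y
  y_anti[split$test[[1]]] <- -y[split$test[[1]]] + 2 * mean(y[split$train[[1]]])
  res_a <- fit_predict_split(X, y_anti, split)
  expect_true(res_a$clamped_negative)
  expect_equal(res_a$r, 0)
  expect_lt(res_a$r_raw, 0)

  # constant observed test response: flagged distinctly
  y_const <- y
  y_const[split$test[[1]]] <- 3
  res_c <- fit_predict_split(X, y_const, split)
  expect_true(res_c$obs_sd_zero)
  expect_equal(res_c$r, 0)
})

test_that("test sounds never influence lambda selection (poisoning probe)", {
  set.seed(15)
  X <- matrix(rnorm(60 * 8), 60, 8)
  plan <- make_split_plan(60, 1, 30, seed = 3)
  split <- plan[1, ]
  y <- as.numeric(X %*% rnorm(8) + 0.5 * rnorm(60))
  res <- fit_predict_split(X, y, split)
  y_poisoned <- y
  y_poisoned[split$test[[1]]] <- 1e6 * rnorm(30)
  res_p <- fit_predict_split(X, y_poisoned, split)
  expect_identical(res$lambda, res_p$lambda)
})

test_that("run_encoding: duplicate stages and permutation equivariance", {
  set.seed(16)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- as.numeric(X %*% rnorm(6) + rnorm(40))
  plan <- make_split_plan(40, 3, 20, seed = 4)
  res <- run_encoding(list(a = X, b = X), cbind(v = y), plan)
  ra <- res[res$stage == 1, c("r", "lambda")]
  rb <- res[res$stage == 2, c("r", "lambda")]
  expect_equal(ra, rb, ignore_attr = TRUE)

  # consistent reordering of sounds (with the plan mapped through it)
  perm <- sample(40)
  plan_p <- plan
  inv <- match(seq_len(40), perm)
  for (i in seq_len(nrow(plan))) {
    plan_p$train[[i]] <- inv[plan$train[[i]]]
    plan_p$test[[i]] <- inv[plan$test[[i]]]
  }
  res_p <- run_encoding(list(a = X[perm, ]), cbind(v = y[perm]), plan_p)
  expect_equal(res[res$stage == 1, ]$r, res_p$r, tolerance = 1e-10)
})

test_that("noiseless voxels recover their source stage", {
  sim <- make_small_sim(n_sounds = 60, n_voxels = 18, noise_sd = 0, seed = 21)
  v123 <- scan_average(sim$voxels)
  colnames(v123) <- as.character(seq_len(ncol(v123)))
  res <- run_encoding(sim$model$activations, v123, sim$plan)
  med <- median_over_splits(res, "r2")
  map <- best_stage_map(med, n_stages = 3)
  truth <- sim$voxels$ground_truth$stage[as.integer(map$voxel)]
  expect_gte(mean(map$best_stage == truth), 0.9)
})

test_that("median_over_splits is invariant to split order", {
  set.seed(17)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- as.numeric(X %*% rnorm(5) + rnorm(40))
  plan <- make_split_plan(40, 4, 20, seed = 5)
  res <- run_encoding(list(a = X), cbind(v = y), plan)
  shuffled <- res[rev(seq_len(nrow(res))), ]
  expect_equal(median_over_splits(res), median_over_splits(shuffled))
})
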