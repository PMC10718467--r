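test_that("spearman_brown closed forms and singular point", {
  expect_equal(spearman_brown(0.5, 3), 0.75)
  expect_equal(spearman_brown(1, 3), 1)
  expect_equal(spearman_brown(1, 7), 1)
  expect_equal(spearman_brown(0.2, 3), 3 * 0.2 / (1 + 2 * 0.2))
  s <- spearman_brown(-0.5, 3)
  expect_true(is.nan(s[1]))
  expect_true(isTRUE(attr(s, "singular")))
})

test_that("measured_reliability: identical scans, noise null, and moderate noise", {
  set.seed(20)
  base <- matrix(rnorm(83 * 5), 83, 5)
  identical_scans <- array(base, dim = c(83, 5, 3))
  expect_equal(measured_reliability(identical_scans), rep(1, 5))

  noise <- array(rnorm(83 * 1000 * 3), dim = c(83, 1000, 3))
  r_null <- measured_reliability(noise)
  expect_lt(abs(mean(r_null)), 0.05)

  # sigma_s = sigma_n voxels: mean reliability near SB(0.5, 3) = 0.75
  sig <- matrix(rnorm(200 * 300), 200, 300)
  resp <- array(0, dim = c(200, 300, 3))
  for (k in 1:3) resp[, , k] <- sig + rnorm(200 * 300)
  expect_lt(abs(mean(measured_reliability(resp)) - 0.75), 0.05)
})

test_that("prediction_reliability mirrors measured_reliability on predictions", {
  set.seed(21)
  p <- matrix(rnorm(82 * 4), 82, 4)
  expect_equal(prediction_reliability(list(p, p, p)), rep(1, 4))
  zero <- matrix(0, 82, 4)
  r0 <- prediction_reliability(list(zero, zero, zero))
  expect_equal(r0, rep(0, 4))
})

test_that("critical_r reproduces the printed floors and is decreasing", {
  expect_equal(round(critical_r(83), 3), 0.182)
  expect_equal(round(critical_r(82), 3), 0.183)
  expect_lt(critical_r(1e6), 0.002)
  ns <- c(10, 50, 100, 1000)
  expect_true(all(diff(critical_r(ns)) < 0))
  expect_error(critical_r(3), ">= 4")
})

test_that("corrected_r2: closed form, floors, clipping, monotonicity", {
  expect_equal(corrected_r2(0.6, 0.8, 0.9, k_meas = 0.1, k_pred = 0.1), 0.5)
  # reliability below the floor: denominator uses the floor
  expect_equal(
    corrected_r2(0.3, 0.1, 0.9),
    0.09 / (critical_r(83) * 0.9)
  )
  expect_equal(corrected_r2(0.9, 0.5, 0.5, k_meas = 0.1, k_pred = 0.1), 1)
  rel <- seq(0.2, 1, by = 0.1)
  vals <- corrected_r2(0.3, rel, 0.9)
  expect_true(all(diff(vals) <= 0))
})

test_that("selection_reliability: geometry and vector-algebra oracle", {
  v <- rnorm(20)
  expect_equal(selection_reliability(v, 2 * v), 1)
  a <- c(1, 0, 0)
  b <- c(0, 1, 0)
  expect_equal(selection_reliability(a, b), 0)
  set.seed(22)
  v12 <- rnorm(30)
  v3 <- rnorm(30)
  proj <- (sum(v12 * v3) / sum(v3^2)) * v3
  oracle <- 1 - sqrt(sum((v12 - proj)^2)) / sqrt(sum(v12^2))
  expect_equal(selection_reliability(v12, v3), oracle, tolerance = 1e-12)
  sq <- selection_reliability(v12, v3, squared = TRUE)
  expect_equal(sq, 1 - sum((v12 - proj)^2) / sum(v12^2), tolerance = 1e-12)
  z <- selection_reliability(rep(0, 5), v3[1:5])
  expect_equal(as.numeric(z), 0)
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("screen_voxels: zero-noise all pass, pure noise rarely passes", {
  sim <- make_small_sim(n_sounds = 40, n_voxels = 12, noise_sd = 0, seed = 23)
  expect_message(scr <- screen_voxels(sim$voxels), "skipped")
  expect_true(all(scr$pass))

  set.seed(24)
  noise <- array(rnorm(165 * 400 * 3), dim = c(165, 400, 3))
  scr_n <- suppressMessages(screen_voxels(noise, threshold = 0.3))
  expect_lt(mean(scr_n$pass), 0.05)
  scr_all <- suppressMessages(screen_voxels(noise, threshold = 0))
  expect_true(all(scr_all$pass))
})

test_that("noiseless voxels: prediction reliability 1 and corrected R2 = 1", {
  sim <- make_small_sim(n_sounds = 50, n_voxels = 9, noise_sd = 0, seed = 25)
  plan <- make_split_plan(50, 2, 25, seed = 25)
  fit <- run_encoding_corrected(sim$model$activations, sim$voxels, plan)
  truth <- sim$voxels$ground_truth
  at_true <- dplyr::inner_join(
    fit$results,
    tibble::tibble(voxel = truth$voxel, true_stage = truth$stage),
    by = "voxel"
  )
  at_true <- at_true[at_true$stage == at_true$true_stage, ]
  expect_true(all(at_true$r_pred > 1 - 1e-6))
  expect_true(all(at_true$r_meas > 1 - 1e-6))
  expect_true(all(at_true$r2_corrected > 1 - 1e-4))
})
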