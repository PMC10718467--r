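test_that("generate_stimuli: lengths, determinism, RMS contract", {
  s <- generate_stimuli(165, 2.0, 20000, seed = 0)
  expect_length(s$waveforms, 165)
  expect_true(all(vapply(s$waveforms, length, integer(1)) == 40000))
  rms_vals <- vapply(s$waveforms, function(w) sqrt(mean(w^2)), numeric(1))
  expect_true(all(abs(rms_vals - 0.1) <= 1e-9))

  a <- generate_stimuli(6, 0.2, 8000, seed = 3)
  b <- generate_stimuli(6, 0.2, 8000, seed = 3)
  expect_identical(a, b)

  expect_error(generate_stimuli(5, -1, 8000), "positive")
  expect_error(generate_stimuli(1, 1, 8000), ">= 2")
})

test_that("generate_model: shapes, rectification, degenerate input", {
  feats <- matrix(rnorm(165 * 30), 165, 30)
  gm <- generate_model(4, c(50, 50, 50, 50), feats, seed = 1)
  expect_length(gm$activations, 4)
  for (a in gm$activations) {
    expect_equal(dim(a), c(165, 50))
    expect_true(min(a) >= 0)
  }

  # all-zero input: every stage's activations equal its rectified propagated
  # biases, identical across sounds
  zfeats <- matrix(0, 10, 30)
  gz <- generate_model(3, 8, zfeats, seed = 2)
  for (a in gz$activations) {
    expect_true(all(a == matrix(a[1, ], nrow(a), ncol(a), byrow = TRUE)))
  }
  expect_equal(gz$activations[[1]][1, ], pmax(gz$model$stages[[1]]$b, 0),
               ignore_attr = TRUE)

  expect_error(compute_activations(gm$model, feats[, 1:5]), "columns")
})

test_that("generate_voxels: zero-noise scans identical; labels verbatim", {
  sim <- make_small_sim(n_sounds = 30, n_voxels = 9, noise_sd = 0)
  r <- sim$voxels$responses
  expect_identical(r[, , 1], r[, , 2])
  expect_identical(r[, , 1], r[, , 3])
  for (v in seq_len(dim(r)[2])) {
    expect_equal(cor(r[, v, 1], r[, v, 2]), 1)
  }
  plan <- hierarchy_voxel_plan(3, 8, 2, primary_stage = 1, nonprimary_stage = 3)
  expect_true(all(plan$stage[plan$roi == "primary"] == 1))
  expect_true(all(plan$stage[plan$roi == "posterior"] == 3))
  vox <- generate_voxels(sim$model$activations, plan, seed = 4)
  expect_identical(vox$roi, plan$roi)
  expect_identical(vox$participant, plan$participant)
  expect_identical(vox$ground_truth$stage, plan$stage)

  plan$noise_sd <- -1
  expect_error(generate_voxels(sim$model$activations, plan), "nonnegative")
})

test_that("generate_voxels: scan-pair correlation matches rho_true at sigma_s = sigma_n", {
  set.seed(11)
  feats <- matrix(rnorm(1000 * 10), 1000, 10)
  gm <- generate_model(2, 10, feats, seed = 11)
  plan <- hierarchy_voxel_plan(2, n_voxels = 60, n_participants = 2, noise_sd = 1)
  vox <- generate_voxels(gm$activations, plan, n_scans = 3, seed = 11)
  pair_r <- vapply(seq_len(60), function(v) {
    cor(vox$responses[, v, 1], vox$responses[, v, 2])
  }, numeric(1))
  expect_true(abs(mean(pair_r) - 0.5) < 0.05)
  expect_equal(unique(vox$ground_truth$rho_true), 0.5)
  expect_equal(unique(vox$ground_truth$rho_avg), 0.75)
})

test_that("generate_components: 6 labeled nonconstant columns, deterministic", {
  sim <- make_small_sim(n_sounds = 30)
  c1 <- generate_components(sim$model$activations, seed = 5)
  c2 <- generate_components(sim$model$activations, seed = 5)
  expect_identical(c1, c2)
  expect_equal(ncol(c1$responses), 6)
  expect_equal(
    colnames(c1$responses),
    c("frequency_low", "frequency_high", "spectrotemporal", "pitch",
      "speech", "music")
  )
  expect_true(all(apply(c1$responses, 2, var) > 0))
})

test_that("permute_parameters preserves shapes and per-block multisets", {
  sim <- make_small_sim(n_sounds = 20)
  m <- sim$model$model
  p1 <- permute_parameters(m, seed = 8)
  p2 <- permute_parameters(m, seed = 8)
  expect_identical(p1, p2)
  for (t in seq_along(m$stages)) {
    expect_equal(dim(p1$stages[[t]]$W), dim(m$stages[[t]]$W))
    expect_identical(sort(as.vector(p1$stages[[t]]$W)),
                     sort(as.vector(m$stages[[t]]$W)))
    expect_identical(sort(p1$stages[[t]]$b), sort(m$stages[[t]]$b))
    expect_identical(p1$stages[[t]]$nonlinearity, m$stages[[t]]$nonlinearity)
  }
  # a constant block is unchanged by permutation
  m$stages[[1]]$W[] <- 0.25
  pc <- permute_parameters(m, seed = 9)
  expect_identical(pc$stages[[1]]$W, m$stages[[1]]$W)
})
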