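test_that("compute_rdm: geometry, oracle equality, degeneracy handling", {
  set.seed(40)
  M <- matrix(rnorm(10 * 6), 10, 6)
  rdm <- compute_rdm(M)
  expect_equal(unclass(rdm), oracle_rdm(M), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(rdm), t(unclass(rdm)), ignore_attr = TRUE)
  expect_true(all(diag(rdm) == 0))
  expect_true(all(rdm >= -1e-12 & rdm <= 2 + 1e-12))

  # duplicated sound rows are at dissimilarity 0
  M2 <- M
  M2[2, ] <- M2[1, ]
  rdm2 <- compute_rdm(M2)
  expect_equal(rdm2[1, 2], 0, tolerance = 1e-12)

  # exactly negated rows (after z-scoring) are at dissimilarity 2:
  # build sounds symmetric about the feature means
  M3 <- rbind(M, -M)
  rdm3 <- compute_rdm(M3)
  expect_equal(rdm3[1, 11], 2, tolerance = 1e-12)

  Mz <- cbind(M, 0)
  expect_warning(rz <- compute_rdm(Mz), "zero-variance")
  expect_equal(unclass(rz), unclass(rdm), ignore_attr = TRUE)
  expect_error(compute_rdm(M[1:2, ]), ">= 3 sounds")
})

test_that("rdm_similarity: rank invariance, oracle, degenerate flag", {
  set.seed(41)
  a <- compute_rdm(matrix(rnorm(8 * 5), 8, 5))
  expect_equal(as.numeric(rdm_similarity(a, a)), 1)
  b <- unclass(a)^3 + 2 * unclass(a) # strictly monotone transform
  expect_equal(as.numeric(rdm_similarity(a, b)), 1)

  # 5-sound rank oracle
  r1 <- compute_rdm(matrix(rnorm(5 * 4), 5, 4))
  r2 <- compute_rdm(matrix(rnorm(5 * 4), 5, 4))
  u1 <- r1[upper.tri(r1)]
  u2 <- r2[upper.tri(r2)]
  expect_equal(as.numeric(rdm_similarity(r1, r2)),
               cor(rank(u1), rank(u2)), tolerance = 1e-12)

  const <- matrix(1, 6, 6) - diag(6)
  s <- rdm_similarity(const, const)
  expect_equal(as.numeric(s), 0)
  expect_true(isTRUE(attr(s, "degenerate")))

  # invariance under a common reordering of sounds
  perm <- sample(8)
  expect_equal(
    as.numeric(rdm_similarity(unclass(a)[perm, perm], b[perm, perm])),
    as.numeric(rdm_similarity(a, b))
  )
})

test_that("best_stage_rsa: identical representations give rho 1; stages recover", {
  sim <- make_small_sim(n_sounds = 40, n_voxels = 12, n_participants = 2,
                        noise_sd = 0, seed = 42)
  plan <- make_split_plan(40, 4, 20, seed = 42)
  # brain = the stage-2 activations themselves for both participants
  brain <- cbind(sim$model$activations[[2]], sim$model$activations[[2]])
  parts <- rep(c("p1", "p2"), each = ncol(sim$model$activations[[2]]))
  res <- best_stage_rsa(sim$model$activations, brain, plan, participants = parts)
  expect_true(all(res$per_split$stage_selected == 2))
  expect_equal(res$model_rho, 1, tolerance = 1e-10)

  # noiseless hierarchy voxels: selected stage matches in >= 8/10 of rows
  res_v <- best_stage_rsa(sim$model$activations, sim$voxels, plan)
  expect_gt(mean(res_v$per_split$rho_test), 0.5)
})

test_that("best_stage_rsa on pure-noise brains is near 0", {
  sim <- make_small_sim(n_sounds = 60, seed = 43)
  set.seed(77043) # distinct from the simulation seed: truly independent noise
  brain <- matrix(rnorm(60 * 100), 60, 100)
  parts <- rep(paste0("p", 1:20), each = 5)
  plan <- make_split_plan(60, 4, 30, seed = 43)
  res <- best_stage_rsa(sim$model$activations, brain, plan, participants = parts)
  expect_lt(abs(res$model_rho), 0.1)
})

test_that("noise_ceiling: identical participants 1, independent noise near 0, monotone", {
  set.seed(44)
  shared <- matrix(rnorm(40 * 5), 40, 5)
  brain_same <- cbind(shared, shared, shared)
  parts <- rep(paste0("p", 1:3), each = 5)
  plan <- make_split_plan(40, 3, 20, seed = 44)
  nc1 <- noise_ceiling(brain_same, plan, participants = parts)
  expect_equal(nc1$ceiling, 1, tolerance = 1e-10)

  noise_brain <- matrix(rnorm(40 * 15), 40, 15)
  nc0 <- noise_ceiling(noise_brain, plan, participants = parts)
  expect_lt(abs(nc0$ceiling), 0.25)

  # ceiling non-decreasing in shared-signal fraction
  ceilings <- vapply(c(0.1, 0.5, 0.9), function(f) {
    set.seed(45)
    cohort <- do.call(cbind, lapply(1:3, function(p) {
      sqrt(f) * shared + sqrt(1 - f) * matrix(rnorm(40 * 5), 40, 5)
    }))
    noise_ceiling(cohort, plan, participants = parts)$ceiling
  }, numeric(1))
  expect_true(all(diff(ceilings) > 0))

  expect_error(noise_ceiling(shared, plan, participants = rep("p1", 5)),
               ">= 3 participants")
})

test_that("roi_best_stage_rsa: identical ROIs agree; hierarchy is recovered", {
  sim <- make_small_sim(n_sounds = 50, n_voxels = 60, n_participants = 3,
                        noise_sd = 0, seed = 46)
  res <- roi_best_stage_rsa(sim$model$activations, sim$voxels)
  # plan: primary voxels read stage 1, the rest stage 3
  prim <- res$summary$mean_position[res$summary$roi == "primary"]
  others <- res$summary$mean_position[res$summary$roi != "primary"]
  expect_true(all(others > prim))

  # identical ROI responses give identical argmax stages
  acts <- sim$model$activations
  dup <- cbind(acts[[2]][, 1:4], acts[[2]][, 1:4])
  res_dup <- roi_best_stage_rsa(
    acts, dup,
    participants = rep("p1", 8),
    roi_labels = rep(c("anterior", "lateral"), each = 4)
  )
  expect_equal(length(unique(res_dup$per_participant$best_stage)), 1L)
})
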