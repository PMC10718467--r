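# Brute-force oracles, written independently of the package implementations.

# Ridge normal equation by dense solve: (X'X + n*lambda*I) w = X'y
oracle_ridge <- function(X, y, lambda, n = nrow(X)) {
  d <- ncol(X)
  solve(crossprod(X) + n * lambda * diag(d), crossprod(X, as.matrix(y)))
}

# RDM by explicit double loop over sound pairs after per-feature z-scoring
oracle_rdm <- function(M) {
  z <- apply(M, 2, function(col) (col - mean(col)) / sd(col))
  n <- nrow(M)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) out[i, j] <- 1 - cor(z[i, ], z[j, ])
    }
  }
  out
}

# Effective dimensionality from covariance eigenvalues
oracle_ed <- function(M, zscore = FALSE) {
  if (zscore) {
    sds <- apply(M, 2, sd)
    M <- M[, sds > 0, drop = FALSE]
    X <- scale(M)
  } else {
    X <- scale(M, center = TRUE, scale = FALSE)
  }
  lam <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  sum(lam)^2 / sum(lam^2)
}

# Leave-one-out mean squared error by explicit refitting, demeaning with the
# reduced training set's means each time (matching the hat-matrix identity on
# the centered full training set up to the standard LOO algebra).
oracle_loo_mse <- function(X, y, lambda) {
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  errs <- vapply(seq_len(n), function(i) {
    w <- solve(
      crossprod(Xc[-i, , drop = FALSE]) + n * lambda * diag(ncol(X)),
      crossprod(Xc[-i, , drop = FALSE], yc[-i])
    )
    # hat-identity LOO keeps the full-set centering, so the oracle must too
    as.numeric(yc[i] - Xc[i, , drop = FALSE] %*% w)^2
  }, numeric(1))
  mean(errs)
}

# Small deterministic simulation used by several tests: a model hierarchy
# with voxels reading out known stages.
make_small_sim <- function(n_sounds = 60, n_stages = 3, units = 10,
                           n_voxels = 18, n_participants = 3, noise_sd = 0,
                           seed = 7) {
  set.seed(seed)
  feats <- matrix(rnorm(n_sounds * 15), n_sounds, 15)
  m <- generate_model(n_stages, units, feats, seed = seed)
  plan <- make_split_plan(n_sounds, 10, n_sounds %/% 2, seed = seed)
  vox <- generate_voxels(
    m$activations,
    hierarchy_voxel_plan(n_stages, n_voxels, n_participants, noise_sd = noise_sd),
    n_scans = 3, seed = seed
  )
  list(features = feats, model = m, plan = plan, voxels = vox)
}
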