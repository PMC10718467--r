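#' Generate a synthetic stimulus set
#'
#' Produces a deterministic, seeded set of equal-duration synthetic sounds —
#' a mixture of harmonic tone complexes, amplitude-modulated noise, and
#' noise bursts — standing in for a natural-sound stimulus set. Every
#' waveform is scaled to a fixed RMS amplitude.
#'
#' @param n_sounds Number of sounds (>= 2).
#' @param duration_s Duration of every sound in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Master seed; the generator is bit-reproducible given the seed.
#' @param rms_target RMS amplitude of every waveform.
#' @return An object of class `stimulus_set`: list with `sound_ids`,
#'   `waveforms` (list of numeric vectors), `sample_rate`, `duration_s`.
#' @export
generate_stimuli <- function(n_sounds, duration_s = 2, sample_rate = 20000,
                             seed = 1, rms_target = 0.1) {
  if (n_sounds < 2) stop("n_sounds must be >= 2", call. = FALSE)
  if (duration_s <= 0 || sample_rate <= 0) {
    stop("duration_s and sample_rate must be positive", call. = FALSE)
  }
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  types <- c("tone_complex", "am_noise", "noise_burst")
  with_seed(substream_seed(seed, "stimuli"), {
    waveforms <- vector("list", n_sounds)
    ids <- sprintf("sound_%03d", seq_len(n_sounds))
    for (i in seq_len(n_sounds)) {
      type <- types[(i - 1) %% length(types) + 1]
      x <- switch(type,
        tone_complex = {
          f0 <- runif(1, 80, 600)
          n_harm <- sample(3:8, 1)
          amps <- runif(n_harm, 0.2, 1)
          rowSums(sapply(seq_len(n_harm), function(h) {
            amps[h] * sin(2 * pi * h * f0 * t + runif(1, 0, 2 * pi))
          }))
        },
        am_noise = {
          fm <- runif(1, 2, 30)
          rnorm(n) * (1 + sin(2 * pi * fm * t + runif(1, 0, 2 * pi)))
        },
        noise_burst = {
          onset <- runif(1, 0, 0.5) * duration_s
          width <- runif(1, 0.2, 0.5) * duration_s
          env <- exp(-((t - onset - width / 2)^2) / (2 * (width / 4)^2))
          rnorm(n) * env
        }
      )
      waveforms[[i]] <- x * (rms_target / rms(x))
    }
    structure(
      list(
        sound_ids = ids, waveforms = waveforms,
        sample_rate = sample_rate, duration_s = duration_s
      ),
      class = "stimulus_set"
    )
  })
}

relu <- function(x) pmax(x, 0)

#' Generate a synthetic multi-stage model
#'
#' Builds a random feed-forward feature hierarchy standing in for a candidate
#' model: stage t activations are a rectified random affine map of stage t-1
#' activations, with stage 0 the provided stimulus features (for instance,
#' time-averaged cochleagram channels). Parameter blocks (weights and biases)
#' are retained on the model object so they can later be permuted to create
#' control models.
#'
#' @param n_stages Number of stages (>= 2).
#' @param units_per_stage Integer vector of stage widths (recycled to
#'   `n_stages`).
#' @param stimulus_features Sounds-by-features matrix of stage-0 features.
#' @param seed Master seed.
#' @return A list with `model` (class `synthetic_model`: stages with parameter
#'   blocks and nonlinearity tags) and `activations` (named list of
#'   sounds-by-units matrices, one per stage, all nonnegative).
#' @export
generate_model <- function(n_stages, units_per_stage, stimulus_features, seed = 1) {
  if (n_stages < 2) stop("n_stages must be >= 2", call. = FALSE)
  if (!is.matrix(stimulus_features)) {
    stop("stimulus_features must be a sounds-by-features matrix", call. = FALSE)
  }
  units <- rep_len(as.integer(units_per_stage), n_stages)
  with_seed(substream_seed(seed, "model"), {
    stages <- vector("list", n_stages)
    d_prev <- ncol(stimulus_features)
    for (t in seq_len(n_stages)) {
      W <- matrix(rnorm(d_prev * units[t], sd = 1 / sqrt(d_prev)), d_prev, units[t])
      b <- rnorm(units[t], sd = 0.1)
      stages[[t]] <- list(W = W, b = b, nonlinearity = "relu")
      d_prev <- units[t]
    }
    model <- structure(
      list(stages = stages, units_per_stage = units, input_dim = ncol(stimulus_features)),
      class = "synthetic_model"
    )
    list(model = model, activations = compute_activations(model, stimulus_features))
  })
}

#' Forward pass of a synthetic model
#'
#' Recomputes the stage activations of a [generate_model()] model from
#' stimulus features; used to derive activations of permuted-parameter
#' control models.
#'
#' @param model A `synthetic_model`.
#' @param stimulus_features Sounds-by-features matrix; column count must
#'   match the model's input dimension.
#' @return Named list of sounds-by-units activation matrices.
#' @export
compute_activations <- function(model, stimulus_features) {
  if (ncol(stimulus_features) != model$input_dim) {
    stop(sprintf(
      "stimulus_features has %d columns but the model expects %d",
      ncol(stimulus_features), model$input_dim
    ), call. = FALSE)
  }
  acts <- vector("list", length(model$stages))
  a <- stimulus_features
  for (t in seq_along(model$stages)) {
    st <- model$stages[[t]]
    a <- relu(sweep(a %*% st$W, 2, st$b, "+"))
    acts[[t]] <- a
  }
  names(acts) <- sprintf("stage_%d", seq_along(acts))
  acts
}

#' Voxel plan for a synthetic cortical hierarchy
#'
#' Assigns each synthetic voxel a participant, an ROI label, a source model
#' stage, and a noise level. The default layout mirrors the primary /
#' non-primary organization probed by the hierarchy analyses: primary voxels
#' read out an early stage, anterior/lateral/posterior voxels a late stage.
#'
#' @param n_stages Number of model stages available.
#' @param n_voxels Total voxels.
#' @param n_participants Participants (voxels split evenly).
#' @param primary_stage,nonprimary_stage Source stages for primary and
#'   non-primary ROIs.
#' @param noise_sd Scan-noise standard deviation relative to unit signal sd.
#' @return A tibble with columns voxel, participant, roi, stage, noise_sd.
#' @export
hierarchy_voxel_plan <- function(n_stages, n_voxels = 200, n_participants = 8,
                                 primary_stage = 1, nonprimary_stage = n_stages,
                                 noise_sd = 1) {
  rois <- c("primary", "anterior", "lateral", "posterior")
  tibble::tibble(
    voxel = seq_len(n_voxels),
    participant = sprintf("p%02d", (seq_len(n_voxels) - 1) %% n_participants + 1),
    roi = rois[(seq_len(n_voxels) - 1) %/% n_participants %% length(rois) + 1],
    stage = ifelse(.data$roi == "primary", primary_stage, nonprimary_stage),
    noise_sd = noise_sd
  )
}

#' Generate synthetic voxel responses
#'
#' Each voxel is a noisy linear readout of one model stage:
#' `responses[s, v, k] = x_s' w_v + eps_svk`, with iid Gaussian scan noise.
#' The noiseless readout is standardized to unit population variance across
#' sounds, so a voxel with noise sd `sigma_n` has single-scan explainable
#' fraction `rho_true = 1 / (1 + sigma_n^2)` and m-scan-average explainable
#' fraction `rho_avg = 1 / (1 + sigma_n^2 / m)`; both are recorded in the
#' ground truth, which the analysis pipeline never consumes.
#'
#' @param activations Named list of stage activation matrices
#'   (sounds x units).
#' @param voxel_plan Tibble with columns voxel, participant, roi, stage and
#'   optionally noise_sd (see [hierarchy_voxel_plan()]).
#' @param noise_sd Default scan-noise sd for voxels without a plan entry.
#' @param n_scans Number of scans (the fMRI protocol uses 3).
#' @param seed Master seed.
#' @return A list of class `voxel_tensor`: `responses`
#'   (sounds x voxels x scans array), `participant`, `roi`, and
#'   `ground_truth` (tibble: voxel, stage, noise_sd, rho_true, rho_avg, and
#'   readout weights as a list column).
#' @export
generate_voxels <- function(activations, voxel_plan, noise_sd = 1, n_scans = 3,
                            seed = 1) {
  if (any(noise_sd < 0) || (("noise_sd" %in% names(voxel_plan)) && any(voxel_plan$noise_sd < 0))) {
    stop("noise_sd must be nonnegative", call. = FALSE)
  }
  if (!("noise_sd" %in% names(voxel_plan))) voxel_plan$noise_sd <- noise_sd
  n_sounds <- nrow(activations[[1]])
  n_vox <- nrow(voxel_plan)
  with_seed(substream_seed(seed, "voxels"), {
    responses <- array(0, dim = c(n_sounds, n_vox, n_scans))
    weights <- vector("list", n_vox)
    for (v in seq_len(n_vox)) {
      A <- activations[[voxel_plan$stage[v]]]
      w <- rnorm(ncol(A))
      signal <- as.vector(A %*% w)
      s_sd <- sqrt(mean((signal - mean(signal))^2))
      if (s_sd > 0) signal <- (signal - mean(signal)) / s_sd
      weights[[v]] <- w
      sn <- voxel_plan$noise_sd[v]
      for (k in seq_len(n_scans)) {
        responses[, v, k] <- signal + if (sn > 0) rnorm(n_sounds, sd = sn) else 0
      }
    }
    gt <- tibble::tibble(
      voxel = voxel_plan$voxel,
      participant = voxel_plan$participant,
      roi = voxel_plan$roi,
      stage = voxel_plan$stage,
      noise_sd = voxel_plan$noise_sd,
      rho_true = 1 / (1 + voxel_plan$noise_sd^2),
      rho_avg = 1 / (1 + voxel_plan$noise_sd^2 / n_scans),
      weights = weights
    )
    structure(
      list(
        responses = responses,
        participant = voxel_plan$participant,
        roi = voxel_plan$roi,
        ground_truth = gt
      ),
      class = "voxel_tensor"
    )
  })
}

#' @export
print.voxel_tensor <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf(
    "<voxel_tensor> %d sounds x %d voxels x %d scans, %d participants\n",
    d[1], d[2], d[3], length(unique(x$participant))
  ))
  invisible(x)
}

#' Average voxel responses across scans
#'
#' @param x A `voxel_tensor`.
#' @param scans Which scans to average (default all).
#' @return A sounds-by-voxels matrix.
#' @export
scan_average <- function(x, scans = seq_len(dim(x$responses)[3])) {
  apply(x$responses[, , scans, drop = FALSE], c(1, 2), mean)
}

#' Generate synthetic component responses
#'
#' Produces six component response profiles, each a (optionally lightly
#' noised) linear readout of a designated model stage — synthetic stand-ins
#' for the six canonical auditory cortical response components (two
#' frequency-selective, spectrotemporal, pitch-, speech-, and
#' music-selective).
#'
#' @param activations Named list of stage activation matrices.
#' @param seed Master seed.
#' @param stages Integer vector (length 6) of source stages; defaults cycle
#'   through the available stages.
#' @param noise_sd Readout noise sd relative to unit signal sd (0 =
#'   noiseless).
#' @return A list with `responses` (sounds x 6 matrix, labeled columns) and
#'   `ground_truth` (tibble: component, stage, noise_sd).
#' @export
generate_components <- function(activations, seed = 1, stages = NULL,
                                noise_sd = 0) {
  n_stages <- length(activations)
  if (is.null(stages)) {
    stages <- rep_len(seq_len(n_stages), 6)
  }
  stopifnot(length(stages) == 6)
  labels <- c(
    "frequency_low", "frequency_high", "spectrotemporal",
    "pitch", "speech", "music"
  )
  n_sounds <- nrow(activations[[1]])
  with_seed(substream_seed(seed, "components"), {
    responses <- matrix(0, nrow = n_sounds, ncol = 6,
                        dimnames = list(NULL, labels))
    for (j in 1:6) {
      A <- activations[[stages[j]]]
      w <- rnorm(ncol(A))
      signal <- as.vector(A %*% w)
      s_sd <- sqrt(mean((signal - mean(signal))^2))
      if (s_sd > 0) signal <- (signal - mean(signal)) / s_sd
      responses[, j] <- signal + if (noise_sd > 0) rnorm(n_sounds, sd = noise_sd) else 0
    }
    list(
      responses = responses,
      ground_truth = tibble::tibble(
        component = labels, stage = stages, noise_sd = noise_sd
      )
    )
  })
}

#' Permute the parameter blocks of a synthetic model
#'
#' Replaces every parameter block (weight matrix, bias vector) of the model
#' by a random permutation of its values across all tensor dimensions,
#' preserving shapes, nonlinearity tags, and per-block value multisets —
#' the permuted-parameter control used to test whether structured (rather
#' than merely architecture- and statistics-matched) parameters drive brain
#' predictivity.
#'
#' @param model A `synthetic_model`.
#' @param seed Seed for the permutation.
#' @return A `synthetic_model` with permuted parameter blocks.
#' @export
permute_parameters <- function(model, seed = 1) {
  permute_vec <- function(x) x[sample.int(length(x))]
  with_seed(substream_seed(seed, "permute"), {
    for (t in seq_along(model$stages)) {
      st <- model$stages[[t]]
      W <- st$W
      model$stages[[t]]$W <- matrix(permute_vec(as.vector(W)), nrow(W), ncol(W))
      model$stages[[t]]$b <- permute_vec(st$b)
    }
  })
  model
}
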