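#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader supporting 16-bit PCM and 32-bit IEEE float
#' encodings (the formats this package writes). Multichannel files are
#' returned as a samples-by-channels matrix.
#'
#' @param path Path to a .wav file.
#' @return List with `waveform` (numeric vector, or matrix for multichannel)
#'   and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      chunk <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(chunk[1:2], "integer", 1, size = 2, endian = "little"),
        n_channels = readBin(chunk[3:4], "integer", 1, size = 2, endian = "little"),
        sample_rate = readBin(chunk[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(chunk[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size) {
        stop("truncated WAV data chunk in ", path, call. = FALSE)
      }
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV file (missing fmt or data chunk): ", path, call. = FALSE)
  }
  x <- if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data_raw, "double", length(data_raw) / 4, size = 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bits)",
                 fmt$audio_format, fmt$bits), call. = FALSE)
  }
  if (fmt$n_channels > 1) {
    x <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
  }
  list(waveform = x, sample_rate = fmt$sample_rate)
}

#' Write a WAV file
#'
#' @param waveform Numeric vector in [-1, 1] (clipped if outside for PCM).
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz.
#' @param bit_depth 16 (PCM) or 32 (IEEE float).
#' @return The path, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate, bit_depth = c(16, 32)) {
  bit_depth <- match.arg(as.character(bit_depth[1]), c("16", "32"))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(waveform)
  if (bit_depth == "16") {
    fmt_code <- 1L
    bytes_per <- 2L
    payload <- writeBin(
      as.integer(round(pmax(pmin(waveform, 1 - 1 / 32768), -1) * 32768)),
      raw(), size = 2, endian = "little"
    )
  } else {
    fmt_code <- 3L
    bytes_per <- 4L
    payload <- writeBin(as.double(waveform), raw(), size = 4, endian = "little")
  }
  data_size <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(as.integer(bytes_per * 8), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}

#' Write a stimulus set as WAV files with a manifest
#'
#' @param stimuli A [generate_stimuli()] object.
#' @param dir Output directory (created if needed).
#' @param bit_depth Passed to [write_wav()].
#' @return Path of the manifest CSV, invisibly.
#' @export
write_stimulus_set <- function(stimuli, dir, bit_depth = 32) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s.wav", stimuli$sound_ids)
  for (i in seq_along(stimuli$waveforms)) {
    write_wav(stimuli$waveforms[[i]], file.path(dir, files[i]),
              stimuli$sample_rate, bit_depth)
  }
  manifest <- data.frame(sound_id = stimuli$sound_ids, filename = files)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

sanitize_key <- function(key) gsub("[^A-Za-z0-9_.-]", "_", key)

#' Write a keyed matrix container
#'
#' Plain-text container for keyed numeric arrays and label vectors: one CSV
#' (full double precision) or text file per key plus a JSON manifest holding
#' key order, dimensions, and storage mode. Keys follow the layout
#' `stages/<i>/activations`, `voxels/responses`, `voxels/participant`,
#' `voxels/roi`; arrays with more than 2 dimensions are stored flattened with
#' their dimensions recorded in the manifest. Round trips are exact.
#'
#' @param container Named list of matrices/arrays/numeric or character
#'   vectors.
#' @param path Directory to write (created if needed).
#' @return `path`, invisibly.
#' @export
write_matrix_container <- function(container, path) {
  stopifnot(is.list(container), !is.null(names(container)))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (key in names(container)) {
    x <- container[[key]]
    file <- paste0(sanitize_key(key), if (is.character(x)) ".txt" else ".csv")
    if (is.character(x)) {
      writeLines(x, file.path(path, file), useBytes = TRUE)
      entries[[length(entries) + 1]] <- list(
        key = key, file = file, mode = "character", dim = length(x)
      )
    } else {
      dims <- if (is.null(dim(x))) length(x) else dim(x)
      writeLines(format(as.vector(x), digits = 17, trim = TRUE, scientific = TRUE),
                 file.path(path, file))
      entries[[length(entries) + 1]] <- list(
        key = key, file = file, mode = "numeric", dim = as.integer(dims)
      )
    }
  }
  manifest <- list(container = "audenc-matrix-container", version = 1L,
                   entries = entries)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a keyed matrix container
#'
#' @param path Container directory written by [write_matrix_container()].
#' @param keys Optional subset of keys; a missing key raises a schema error
#'   naming it.
#' @return Named list of arrays / vectors, in manifest (write) order.
#' @export
read_matrix_container <- function(path, keys = NULL) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mpath)
  available <- vapply(manifest$entries, function(e) e$key, character(1))
  if (is.null(keys)) keys <- available
  missing <- setdiff(keys, available)
  if (length(missing) > 0) {
    stop("container is missing key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (key in keys) {
    e <- manifest$entries[[match(key, available)]]
    fp <- file.path(path, e$file)
    dims <- as.integer(unlist(e$dim))
    if (identical(e$mode, "character")) {
      out[[key]] <- readLines(fp)
    } else {
      v <- as.numeric(readLines(fp))
      if (length(v) != prod(dims)) {
        stop(sprintf("key '%s': expected %d values, found %d",
                     key, prod(dims), length(v)), call. = FALSE)
      }
      out[[key]] <- if (length(dims) > 1) array(v, dim = dims) else v
    }
  }
  out
}

#' Default pipeline configuration
#'
#' A small, fast end-to-end configuration: synthetic stimuli, a reduced
#' cochlear filterbank, a 3-stage synthetic model, and a modest voxel cohort.
#' All sizes are configurable; the cross-validation protocol (split counts,
#' regularization grid, reliability floors) follows the analysis defaults.
#'
#' @param seed Master seed.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    n_sounds = 24,
    duration_s = 0.5,
    sample_rate = 4000,
    f_low = 50,
    f_high = 1800,
    n_cochlear_filters = 30,
    env_rate = 200,
    n_stages = 3,
    units_per_stage = 20,
    n_voxels = 48,
    n_participants = 4,
    noise_sd = 1,
    n_splits = 10,
    n_train = 12
  ), class = c("run_config", "list"))
}

required_config_fields <- c(
  "seed", "n_sounds", "duration_s", "sample_rate", "f_low", "f_high",
  "n_cochlear_filters", "env_rate", "n_stages", "units_per_stage",
  "n_voxels", "n_participants", "noise_sd", "n_splits", "n_train"
)

#' Validate a pipeline configuration
#'
#' @param config A config list.
#' @return The config, invisibly; errors name the offending field.
#' @export
validate_config <- function(config) {
  missing <- setdiff(required_config_fields, names(config))
  if (length(missing) > 0) {
    stop("config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in required_config_fields) {
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1 || !is.finite(config[[f]])) {
      stop(sprintf("config field '%s' must be a single finite number", f),
           call. = FALSE)
    }
  }
  if (config$n_train >= config$n_sounds) {
    stop("config: n_train must be smaller than n_sounds", call. = FALSE)
  }
  if (config$f_high >= config$sample_rate / 2) {
    stop("config: f_high must be below Nyquist", call. = FALSE)
  }
  invisible(config)
}

#' Save / load a pipeline configuration (YAML)
#'
#' @param config A config list.
#' @param path YAML file path.
#' @return `save_run_config()` returns the path invisibly;
#'   `load_run_config()` returns the validated config.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  validate_config(config)
  structure(config, class = c("run_config", "list"))
}

config_hash <- function(config) {
  substream_seed(0, yaml::as.yaml(unclass(config)[order(names(config))]))
}

#' Run the full synthetic pipeline
#'
#' Orchestrates the end-to-end analysis on synthetic data: stimulus
#' generation, cochleagram features, synthetic model and voxel/component
#' generation, noise-corrected voxelwise encoding, component prediction with
#' split-based stage selection, RSA with noise ceiling, best-stage
#' summaries, and effective dimensionality. Stages already present in
#' `cache` are reused, making the run resumable. The result embeds a hash of
#' the configuration; reruns with the same config are identical.
#'
#' @param config A [default_config()]-style list.
#' @param cache Optional bundle from a previous (partial) run.
#' @return A named list bundle of class `pipeline_bundle`.
#' @export
run_pipeline <- function(config = default_config(), cache = NULL) {
  validate_config(config)
  bundle <- if (is.null(cache)) list() else cache
  step <- function(name, expr) {
    if (is.null(bundle[[name]])) {
      bundle[[name]] <<- tryCatch(expr, error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      })
    }
    bundle[[name]]
  }

  stimuli <- step("stimuli", generate_stimuli(
    config$n_sounds, config$duration_s, config$sample_rate, seed = config$seed
  ))
  fb <- step("filterbank", build_erb_filterbank(
    config$n_cochlear_filters, config$f_low, config$f_high,
    signal_length = round(config$duration_s * config$sample_rate),
    sample_rate = config$sample_rate
  ))
  features <- step("features", {
    f <- t(vapply(stimuli$waveforms, function(w) {
      rowMeans(compute_cochleagram(w, fb, env_rate = config$env_rate))
    }, numeric(config$n_cochlear_filters)))
    sds <- apply(f, 2, stats::sd)
    sds[sds == 0] <- 1
    scale(f, scale = sds)
  })
  model <- step("model", generate_model(
    config$n_stages, config$units_per_stage, features, seed = config$seed
  ))
  plan <- step("plan", make_split_plan(
    config$n_sounds, config$n_splits, config$n_train, seed = config$seed
  ))
  voxels <- step("voxels", generate_voxels(
    model$activations,
    hierarchy_voxel_plan(config$n_stages, config$n_voxels, config$n_participants,
                         noise_sd = config$noise_sd),
    n_scans = 3, seed = config$seed
  ))
  components <- step("components", generate_components(
    model$activations, seed = config$seed
  ))
  encoding <- step("encoding", run_encoding_corrected(
    model$activations, voxels, plan
  ))
  component_fit <- step("component_fit", {
    rec <- predict_components(model$activations, components, plan)
    iters <- best_stage_split_selection(rec, n_select = config$n_splits %/% 2,
                                        n_eval = config$n_splits - config$n_splits %/% 2,
                                        seed = config$seed)
    list(records = rec, iterations = iters,
         summary = summarize_stage_selection(iters))
  })
  rsa <- step("rsa", {
    bs <- best_stage_rsa(model$activations, voxels, plan)
    nc <- if (config$n_participants >= 3) noise_ceiling(voxels, plan) else NULL
    list(best_stage = bs, noise_ceiling = nc)
  })
  summaries <- step("summaries", {
    med <- median_over_splits(
      dplyr::rename(encoding$results, target = "voxel"), "r2_corrected"
    )
    map <- best_stage_map(med, n_stages = config$n_stages)
    meta <- tibble::tibble(
      voxel = seq_along(voxels$participant),
      participant = voxels$participant, roi = voxels$roi
    )
    list(medians = med, map = map, roi = roi_best_stage(map, meta))
  })
  ed <- step("ed", {
    tibble::tibble(
      stage = seq_len(config$n_stages),
      ed_regression = vapply(model$activations, function(a) {
        as.numeric(effective_dim(a, "demean"))
      }, numeric(1)),
      ed_rsa = vapply(model$activations, function(a) {
        as.numeric(suppressWarnings(effective_dim(a, "zscore")))
      }, numeric(1))
    )
  })
  bundle$config <- config
  bundle$config_hash <- config_hash(config)
  class(bundle) <- c("pipeline_bundle", "list")
  bundle
}
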