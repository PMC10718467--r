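#' Build the spectrotemporal modulation filterbank
#'
#' Constructs the linear modulation filterbank applied to the cochleagram:
#' Gabor-like filters tuned to joint spectrotemporal modulations at a grid of
#' spectral scales (cycles/ERB) and temporal rates (Hz), with both upward and
#' downward sweep directions, plus purely spectral and purely temporal
#' filters. With the default 6 scales and 8 rates this yields
#' 6 x 8 x 2 = 96 joint filters + 6 spectral + 8 temporal = 110 filters.
#'
#' Joint filters are built as the real part of the product of analytic
#' spectral and temporal Gabors (constant-Q: the Gaussian envelope width is
#' one modulation period); `direction = "up"` filters respond to ripples
#' whose peak frequency increases over time, `"down"` to the reverse. Purely
#' spectral filters have an impulsive temporal profile and purely temporal
#' filters an impulsive spectral profile. All impulse responses are
#' normalized to unit L2 norm.
#'
#' @param scales Spectral modulation center frequencies, cycles/ERB.
#' @param rates Temporal modulation center frequencies, Hz.
#' @param n_channels Number of cochleagram frequency channels the bank is
#'   designed for.
#' @param env_rate Cochleagram envelope sampling rate, Hz.
#' @param erb_per_channel ERB-number spacing between adjacent cochleagram
#'   channels (converts cycles/ERB to cycles/channel). Default matches the
#'   default 211-channel, 50 Hz--10 kHz cochlear filterbank.
#' @param max_spectral_support,max_temporal_support Caps (in samples) on the
#'   impulse-response extents, matching the zero-padding used by
#'   [spectrotemporal_features()].
#' @param include_dc If `TRUE`, append a DC (unmodulated Gaussian) filter.
#' @return A tibble of class `modulation_filterbank` with one row per filter:
#'   `scale`, `rate`, `direction` (up/down/none), `kind`
#'   (joint/spectral/temporal/dc), and `ir`, a list column of
#'   frequency-by-time impulse response matrices.
#' @export
build_modulation_filterbank <- function(scales = c(0.0625, 0.125, 0.25, 0.5, 1, 2),
                                        rates = c(0.5, 1, 2, 4, 8, 16, 32, 64),
                                        n_channels = 211,
                                        env_rate = 200,
                                        erb_per_channel = (freq_to_erb(10000) - freq_to_erb(50)) / 210,
                                        max_spectral_support = 801,
                                        max_temporal_support = 211,
                                        include_dc = FALSE) {
  # analytic Gabor sampled on an odd-length symmetric grid
  gabor <- function(freq_per_sample, max_support) {
    sigma <- 1 / freq_per_sample # envelope std = one modulation period
    half <- min(ceiling(3 * sigma), (max_support - 1) / 2)
    t <- seq(-half, half)
    exp(-t^2 / (2 * sigma^2)) * exp(2i * pi * freq_per_sample * t)
  }
  impulse <- function(max_support) complex(real = 1) # delta profile

  normalize <- function(m) {
    nrm <- sqrt(sum(m^2))
    if (nrm > 0) m / nrm else m
  }

  rows <- list()
  for (s in scales) {
    omega <- s * erb_per_channel # cycles per channel
    gs <- gabor(omega, max_spectral_support)
    for (r in rates) {
      w <- r / env_rate # cycles per frame
      gt <- gabor(w, max_temporal_support)
      # Re[gs (x) gt] has spectral energy where sign(spectral freq) ==
      # sign(temporal freq): peaks drift toward lower channels over time.
      down <- normalize(Re(outer(gs, gt)))
      up <- normalize(Re(outer(gs, Conj(gt))))
      rows[[length(rows) + 1]] <- tibble::tibble(
        scale = s, rate = r, direction = "down", kind = "joint", ir = list(down)
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        scale = s, rate = r, direction = "up", kind = "joint", ir = list(up)
      )
    }
  }
  for (s in scales) {
    omega <- s * erb_per_channel
    gs <- gabor(omega, max_spectral_support)
    ir <- normalize(Re(outer(gs, impulse())))
    rows[[length(rows) + 1]] <- tibble::tibble(
      scale = s, rate = NA_real_, direction = "none", kind = "spectral", ir = list(ir)
    )
  }
  for (r in rates) {
    w <- r / env_rate
    gt <- gabor(w, max_temporal_support)
    ir <- normalize(Re(outer(impulse(), gt)))
    rows[[length(rows) + 1]] <- tibble::tibble(
      scale = NA_real_, rate = r, direction = "none", kind = "temporal", ir = list(ir)
    )
  }
  if (include_dc) {
    gs <- Re(gabor(scales[1] * erb_per_channel, max_spectral_support))
    ir <- normalize(outer(abs(gs), 1))
    rows[[length(rows) + 1]] <- tibble::tibble(
      scale = 0, rate = 0, direction = "none", kind = "dc", ir = list(ir)
    )
  }

  fb <- dplyr::bind_rows(rows)
  # deterministic ordering: joint by (scale, rate, direction), then spectral
  # by scale, then temporal by rate
  kind_order <- c(joint = 1, spectral = 2, temporal = 3, dc = 4)
  fb <- fb[order(kind_order[fb$kind], fb$scale, fb$rate, fb$direction), ]
  fb$filter <- seq_len(nrow(fb))
  fb <- fb[, c("filter", "scale", "rate", "direction", "kind", "ir")]
  structure(fb,
    n_channels = as.integer(n_channels),
    env_rate = env_rate,
    erb_per_channel = erb_per_channel,
    class = c("modulation_filterbank", class(fb))
  )
}

# 2-D linear convolution via FFT of a pre-padded cochleagram with one filter,
# cropped to "same" extent (aligned at the filter center).
conv2_same <- function(padded_fft, pad_dim, ir, out_dim) {
  irp <- matrix(0, nrow = pad_dim[1], ncol = pad_dim[2])
  irp[seq_len(nrow(ir)), seq_len(ncol(ir))] <- ir
  out <- Re(fft(padded_fft * fft(irp), inverse = TRUE)) / prod(pad_dim)
  ci <- (nrow(ir) + 1) %/% 2
  cj <- (ncol(ir) + 1) %/% 2
  out[ci:(ci + out_dim[1] - 1), cj:(cj + out_dim[2] - 1), drop = FALSE]
}

#' Time-averaged spectrotemporal modulation power features
#'
#' Applies every filter of a modulation filterbank to a cochleagram as a 2-D
#' convolution with zero padding in frequency and time, squares the filter
#' outputs at every time step, and averages the squared outputs over time for
#' each frequency channel. The resulting per-filter, per-channel power values
#' are the regressors of the spectrotemporal baseline model.
#'
#' @param cochleagram A channels-by-frames matrix (see
#'   [compute_cochleagram()]); the channel count must match the filterbank
#'   design.
#' @param filterbank A [build_modulation_filterbank()] object.
#' @param pad_freq,pad_time Zero padding in frequency and time samples.
#' @return A numeric vector of length `n_filters * n_channels` (filter-major
#'   order), all values nonnegative, with a `feature_info` attribute tibble
#'   mapping positions to (filter, channel).
#' @export
spectrotemporal_features <- function(cochleagram, filterbank,
                                     pad_freq = 800, pad_time = 211) {
  nc <- nrow(cochleagram)
  nt <- ncol(cochleagram)
  if (nc != attr(filterbank, "n_channels")) {
    stop(sprintf(
      "cochleagram has %d channels but the filterbank was designed for %d",
      nc, attr(filterbank, "n_channels")
    ), call. = FALSE)
  }
  max_ir_f <- max(vapply(filterbank$ir, nrow, integer(1)))
  max_ir_t <- max(vapply(filterbank$ir, ncol, integer(1)))
  p1 <- nc + max(pad_freq, max_ir_f - 1)
  p2 <- nt + max(pad_time, max_ir_t - 1)
  padded <- matrix(0, nrow = p1, ncol = p2)
  padded[seq_len(nc), seq_len(nt)] <- unclass(cochleagram)
  padded_fft <- fft(padded)

  n_filt <- nrow(filterbank)
  power <- matrix(0, nrow = n_filt, ncol = nc)
  for (i in seq_len(n_filt)) {
    resp <- conv2_same(padded_fft, c(p1, p2), filterbank$ir[[i]], c(nc, nt))
    power[i, ] <- rowMeans(resp^2)
  }
  values <- as.vector(t(power)) # filter-major: filter 1 channels, filter 2 ...
  info <- tidyr::expand_grid(
    filter = filterbank$filter,
    channel = seq_len(nc)
  )
  attr(values, "feature_info") <- info
  values
}

#' Generate a drifting spectrotemporal ripple
#'
#' Synthesizes a cochleagram-like drifting ripple pattern
#' `1 + cos(2 pi (scale_cyc_per_channel * x -/+ rate_cyc_per_frame * t))`,
#' useful for probing the tuning of modulation filters. `direction = "up"`
#' moves ripple peaks toward higher channels over time.
#'
#' @param n_channels,n_frames Output extent.
#' @param scale Spectral modulation, cycles/ERB.
#' @param rate Temporal modulation, Hz.
#' @param direction "up" or "down".
#' @param env_rate Frame rate, Hz.
#' @param erb_per_channel Channel spacing in ERB numbers.
#' @return A channels-by-frames matrix.
#' @export
make_ripple <- function(n_channels = 211, n_frames = 200, scale = 0.25,
                        rate = 4, direction = c("up", "down"), env_rate = 200,
                        erb_per_channel = (freq_to_erb(10000) - freq_to_erb(50)) / 210) {
  direction <- match.arg(direction)
  sgn <- if (direction == "up") -1 else 1
  omega <- scale * erb_per_channel
  w <- rate / env_rate
  x <- seq_len(n_channels) - 1
  t <- seq_len(n_frames) - 1
  1 + cos(2 * pi * outer(omega * x, sgn * w * t, "+"))
}
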