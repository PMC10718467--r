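#' ERB-number scale conversions
#'
#' Map between frequency in Hz and the Glasberg--Moore ERB-number scale on
#' which cochlear filters are equally spaced.
#'
#' @param f Frequency in Hz.
#' @param e ERB number.
#' @return `freq_to_erb()` returns ERB numbers; `erb_to_freq()` returns Hz.
#' @export
freq_to_erb <- function(f) 21.4 * log10(0.00437 * f + 1)

#' @rdname freq_to_erb
#' @export
erb_to_freq <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Build an ERB-spaced cosine filterbank
#'
#' Constructs a bank of zero-phase bandpass filters whose frequency responses
#' are half-cosine lobes equally spaced and equally wide on the ERB-number
#' axis, together with low-pass and high-pass edge filters that complete the
#' tiling so that the summed squared response is flat (equal to 1) at every
#' frequency from DC to Nyquist. Filters are defined by their samples on the
#' real-FFT frequency grid of a signal of length `signal_length`, so filtering
#' is exactly zero phase (multiplication of the spectrum by a real,
#' nonnegative response).
#'
#' The bank is 4x overcomplete: cosine lobes span `2 * n_edge` steps of the
#' uniform ERB grid and are shifted by one step, and `n_edge` low-pass and
#' `n_edge` high-pass filters (flat-extended half lobes) absorb the residual
#' edge energy. With the defaults this yields 203 bandpass + 4 low-pass +
#' 4 high-pass = 211 filters between 50 Hz and 10 kHz.
#'
#' @param n_filters Total number of filters including edge filters.
#' @param f_low,f_high Passband limits in Hz; `f_high` must be below Nyquist.
#' @param signal_length Length in samples of the signals to be filtered.
#' @param sample_rate Sampling rate in Hz.
#' @param n_edge Number of low-pass (and of high-pass) edge filters.
#' @return An object of class `erb_filterbank`: a list with the
#'   filters-by-frequencies `response` matrix, `center_freqs_hz`,
#'   `freqs_hz` (the rFFT grid), filter `kind` labels, and the design
#'   parameters.
#' @export
build_erb_filterbank <- function(n_filters = 211, f_low = 50, f_high = 10000,
                                 signal_length = 40000, sample_rate = 20000,
                                 n_edge = 4) {
  if (f_low <= 0 || f_high <= f_low) {
    stop("need 0 < f_low < f_high", call. = FALSE)
  }
  if (f_high > sample_rate / 2) {
    stop("f_high must not exceed the Nyquist frequency", call. = FALSE)
  }
  n_band <- n_filters - 2L * n_edge
  if (n_band < 1L) stop("n_filters too small for the requested n_edge", call. = FALSE)

  n_freqs <- floor(signal_length / 2) + 1L
  freqs <- (seq_len(n_freqs) - 1) * sample_rate / signal_length
  e <- freq_to_erb(freqs)

  # Uniform grid on the ERB axis; one grid point per filter center.
  g <- seq(freq_to_erb(f_low), freq_to_erb(f_high), length.out = n_filters)
  delta <- g[2] - g[1]
  half_width <- n_edge * delta # lobes span 2 * n_edge grid steps

  lobe <- function(center) {
    u <- (e - center) / (2 * half_width)
    r <- cos(pi * u)
    r[abs(u) > 0.5] <- 0
    r
  }

  response <- matrix(0, nrow = n_filters, ncol = n_freqs)
  kind <- character(n_filters)
  # low-pass edge filters: flat below their center, falling half lobe above
  for (m in seq_len(n_edge)) {
    center <- g[m]
    r <- lobe(center)
    r[e < center] <- 1
    response[m, ] <- r
    kind[m] <- "lowpass"
  }
  # bandpass cosine lobes
  for (k in seq_len(n_band)) {
    response[n_edge + k, ] <- lobe(g[n_edge + k])
    kind[n_edge + k] <- "bandpass"
  }
  # high-pass edge filters: rising half lobe below their center, flat above
  for (m in seq_len(n_edge)) {
    center <- g[n_filters - n_edge + m]
    r <- lobe(center)
    r[e > center] <- 1
    response[n_filters - n_edge + m, ] <- r
    kind[n_filters - n_edge + m] <- "highpass"
  }
  # 2 * n_edge lobes overlap at interior frequencies and their squares sum to
  # n_edge; rescale so the summed squared response is exactly 1.
  response <- response / sqrt(n_edge)

  structure(
    list(
      response = response,
      center_freqs_hz = erb_to_freq(g),
      freqs_hz = freqs,
      kind = kind,
      n_filters = n_filters,
      n_edge = n_edge,
      f_low = f_low,
      f_high = f_high,
      sample_rate = sample_rate,
      signal_length = as.integer(signal_length),
      erb_step = delta
    ),
    class = "erb_filterbank"
  )
}

#' @export
print.erb_filterbank <- function(x, ...) {
  cat(sprintf(
    "<erb_filterbank> %d filters (%d bandpass + %d lowpass + %d highpass), %.0f-%.0f Hz @ %.0f Hz\n",
    x$n_filters, sum(x$kind == "bandpass"), sum(x$kind == "lowpass"),
    sum(x$kind == "highpass"), x$f_low, x$f_high, x$sample_rate
  ))
  invisible(x)
}

# Analytic (Hilbert) subband envelopes: multiply the one-sided spectrum by the
# filter response and invert; the modulus of the resulting analytic signal is
# the subband envelope.
subband_envelopes <- function(waveform, fb) {
  n <- length(waveform)
  spec <- fft(waveform)
  # analytic-signal weighting of the full spectrum
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  n_freqs <- floor(n / 2) + 1L
  env <- matrix(0, nrow = fb$n_filters, ncol = n)
  base <- spec[seq_len(n_freqs)] * h[seq_len(n_freqs)]
  for (i in seq_len(fb$n_filters)) {
    full <- complex(length.out = n)
    full[seq_len(n_freqs)] <- base * fb$response[i, ]
    env[i, ] <- Mod(fft(full, inverse = TRUE)) / n
  }
  env
}

# Windowed-sinc decimation lowpass: cutoff env_rate/2, Hamming window, length
# 10 * (sample_rate / env_rate) + 1, unit DC gain.
decimation_kernel <- function(sample_rate, env_rate) {
  q <- sample_rate / env_rate
  k_len <- as.integer(10 * q + 1)
  m <- (k_len - 1) / 2
  t <- seq_len(k_len) - 1 - m
  fc <- env_rate / 2 / sample_rate # normalized cutoff
  h <- 2 * fc * sinc_fn(2 * fc * t)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(k_len - 1)) / (k_len - 1))
  h <- h * w
  h / sum(h)
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Valid-mode (no zero padding) FIR filtering followed by decimation.
lowpass_decimate <- function(x, kernel, q) {
  n <- length(x)
  k_len <- length(kernel)
  if (n < k_len) stop("signal shorter than the decimation kernel", call. = FALSE)
  full <- stats::convolve(x, rev(kernel), type = "open")
  valid <- full[k_len:n]
  valid[seq(1, length(valid), by = q)]
}

#' Compute a cochleagram
#'
#' Passes a waveform through an ERB-spaced cosine filterbank, extracts each
#' subband envelope as the magnitude of the analytic signal (Hilbert
#' transform), applies a compressive power nonlinearity, and lowpass filters
#' and downsamples the compressed envelopes to `env_rate` without zero
#' padding. With the default 211-filter bank a 2-second, 20 kHz waveform
#' yields a 211-channel by 390-frame cochleagram.
#'
#' The number of output frames is a pure function of the input length `L`,
#' the decimation factor `q = sample_rate / env_rate`, and the decimation
#' kernel length `K = 10 q + 1`: `frames = floor((L - K) / q) + 1`.
#'
#' @param waveform Numeric vector (mono). A matrix is averaged across columns
#'   to mono with a warning.
#' @param filterbank An [build_erb_filterbank()] object matching the waveform
#'   length and sample rate.
#' @param env_rate Envelope sampling rate in Hz; must divide the sample rate.
#' @param compression Exponent of the compressive nonlinearity applied to the
#'   envelopes (basilar-membrane-like compression).
#' @return A channels-by-frames matrix of class `cochleagram` with attributes
#'   `env_rate`, `center_freqs_hz`, and `compression`.
#' @export
compute_cochleagram <- function(waveform, filterbank, env_rate = 200,
                                compression = 0.3) {
  if (is.matrix(waveform)) {
    warning("multichannel input averaged to mono")
    waveform <- rowMeans(waveform)
  }
  if (anyNA(waveform) || !all(is.finite(waveform))) {
    stop("waveform must be finite with no NA values", call. = FALSE)
  }
  if (length(waveform) != filterbank$signal_length) {
    stop("waveform length does not match the filterbank design length", call. = FALSE)
  }
  sr <- filterbank$sample_rate
  if (sr %% env_rate != 0) {
    stop("env_rate must divide the sample rate", call. = FALSE)
  }
  q <- sr / env_rate
  kernel <- decimation_kernel(sr, env_rate)
  env <- subband_envelopes(waveform, filterbank)
  env <- pmax(env, 0)^compression
  frames <- floor((length(waveform) - length(kernel)) / q) + 1
  out <- matrix(0, nrow = filterbank$n_filters, ncol = frames)
  for (i in seq_len(filterbank$n_filters)) {
    out[i, ] <- lowpass_decimate(env[i, ], kernel, q)
  }
  out <- pmax(out, 0) # FIR ripple can leave tiny negative values
  structure(out,
    env_rate = env_rate,
    center_freqs_hz = filterbank$center_freqs_hz,
    compression = compression,
    class = c("cochleagram", class(out))
  )
}

#' Plot a cochleagram
#'
#' @param object A `cochleagram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cochleagram <- function(object, ...) {
  df <- tidyr::expand_grid(
    channel = seq_len(nrow(object)),
    frame = seq_len(ncol(object))
  )
  df$value <- as.vector(t(unclass(object)[, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$channel, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "envelope") +
    ggplot2::labs(x = "time frame", y = "frequency channel")
}
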