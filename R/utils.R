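#' @importFrom rlang .data
#' @importFrom stats cor fft median qt quantile rnorm runif sd var
NULL

# Deterministic sub-seed for a named random substream. All generators hang off
# one master seed; distinct stream names give decorrelated but reproducible
# streams. Result fits in a 32-bit integer.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(name)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

rms <- function(x) sqrt(mean(x^2))

# Pearson correlation that tolerates zero-variance inputs: returns 0 with a
# "degenerate" attribute instead of NA, matching how undefined correlations
# are handled throughout the pipeline (flagged, not dropped).
safe_cor <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  stats::cor(x, y)
}

assert_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` must contain only finite values", what), call. = FALSE)
  }
  invisible(x)
}
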