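# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population (divisor-N) standard deviation
#'
#' All variability features in the package use the population convention,
#' matching the array-library default the pipeline standardizes against.
#'
#' @param x numeric vector.
#' @return non-negative scalar; 0 for length-1 input.
#' @keywords internal
pop_sd <- function(x) {
  n <- length(x)
  if (n < 1L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

rms <- function(x) sqrt(mean(x^2))

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# Derive a reproducible child seed from a base seed and a stream label;
# kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483561) + 1L
}

# Parabolic interpolation of a peak at index i of y: returns fractional
# offset in [-0.5, 0.5] and interpolated height.
parabolic_peak <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(list(offset = 0, height = y[i]))
  a <- y[i - 1L]; b <- y[i]; c <- y[i + 1L]
  den <- a - 2 * b + c
  if (abs(den) < .Machine$double.eps) return(list(offset = 0, height = b))
  off <- 0.5 * (a - c) / den
  off <- max(-0.5, min(0.5, off))
  list(offset = off, height = b - 0.25 * (a - c) * off)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
}
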