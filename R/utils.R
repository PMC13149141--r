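# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic signal via the one-sided spectrum
#'
#' Returns `x + i*H(x)` where `H` is the Hilbert transform, computed by
#' zeroing the negative-frequency half of the FFT and doubling the positive
#' half (the DC and Nyquist bins are kept once).
#'
#' @param x numeric vector, zero-mean narrowband series.
#' @return complex vector of the same length.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Phase unwrapping (cumulative correction of 2*pi jumps).
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

# Centered moving average with edge shrinkage, window of k samples.
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (k - 1 - half), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Welch power spectral density
#'
#' Hann-windowed, overlapping-segment averaged one-sided PSD, scaled so that
#' `sum(psd) * df` approximates the variance of the (detrended) input.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param seg_len segment length in samples; clipped to `length(x)`.
#' @param overlap fractional overlap between segments.
#' @return list with `freq` (Hz) and `psd` (power density, unit^2/Hz).
#' @keywords internal
#' @noRd
welch_psd <- function(x, fs, seg_len = length(x), overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  # anchor a final segment at the series end so the tail is covered
  starts <- unique(c(starts, n - seg_len + 1L))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1)) # Hann
  wnorm <- sum(w^2)
  nf <- seg_len %/% 2
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    pxx <- Mod(X[2:(nf + 1L)])^2 / (fs * wnorm)
    # one-sided doubling (Nyquist bin kept single for even seg_len)
    pxx <- pxx * 2
    if (seg_len %% 2 == 0) pxx[nf] <- pxx[nf] / 2
    acc <- acc + pxx
  }
  list(freq = (1:nf) * fs / seg_len, psd = acc / length(starts))
}

# Validates a single numeric waveform channel.
check_waveform <- function(x, name = "waveform") {
  if (!is.numeric(x) || length(x) < 2L)
    stop(name, " must be a numeric vector with >= 2 samples", call. = FALSE)
  if (any(!is.finite(x)))
    stop(name, " contains non-finite values", call. = FALSE)
  invisible(x)
}
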