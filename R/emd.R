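#' Ensemble empirical mode decomposition
#'
#' Decomposes a uniformly sampled series into intrinsic mode functions
#' (IMFs) by ensemble-averaged sifting: Gaussian white noise with standard
#' deviation `noise_ratio * sd(x)` is added to the signal, each noisy
#' realization is decomposed by EMD with a fixed number of sifting
#' iterations per mode, and the mode estimates are averaged across the
#' ensemble. Deterministic for a given `seed`.
#'
#' @param x a [uniform_series()] or numeric vector.
#' @param fs sampling rate (Hz); taken from `x` when it is a
#'   [uniform_series()].
#' @param noise_ratio noise amplitude as a fraction of `sd(x)` (default 0.2).
#' @param ensemble number of noise realizations (default 100).
#' @param seed integer seed for the noise generator.
#' @param nsift fixed sifting iterations per mode (default 8).
#' @param max_imf maximum number of modes; default `floor(log2(n)) - 1`.
#' @param merge_ratio ensemble averaging can split one rhythm across two
#'   adjacent mode slots (the slot index varies between noise
#'   realizations); adjacent averaged modes whose mean instantaneous
#'   frequencies differ by less than this ratio are therefore summed back
#'   into one mode. White-noise modes form a dyadic bank (ratio ~2), so
#'   the default 1.5 only consolidates split rhythms. Set to `1` to
#'   disable.
#' @return an `imf_set`: list with `imfs` (matrix, one column per mode,
#'   fastest first), `residual`, `fs`, `kind`, and per-IMF Hilbert
#'   analytics (`amplitude`, `phase`, `freq` matrices).
#' @export
#' @examples
#' u <- uniform_series(sin(2 * pi * 0.3 * seq(0, 299.875, by = 1/8)), fs = 8)
#' s <- eemd(u, seed = 1)
#' s
eemd <- function(x, fs = NULL, noise_ratio = 0.2, ensemble = 100,
                 seed = 1L, nsift = 8L, max_imf = NULL, merge_ratio = 1.5) {
  if (inherits(x, "uniform_series")) { fs <- x$fs; kind <- x$kind; x <- x$values }
  else kind <- "series"
  if (is.null(fs)) stop("fs required when x is a bare vector", call. = FALSE)
  n <- length(x)
  if (n < 64L) stop("eemd needs at least 64 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("eemd input must be finite", call. = FALSE)
  if (is.null(max_imf)) max_imf <- max(1L, floor(log2(n)) - 1L)
  sdx <- stats::sd(x)
  if (sdx == 0) {
    # constant input: no oscillatory mode, everything is residual
    out <- structure(list(imfs = matrix(numeric(0), nrow = n, ncol = 0),
                          residual = x, fs = fs, kind = kind, seed = seed,
                          amplitude = NULL, phase = NULL, freq = NULL),
                     class = "imf_set")
    return(out)
  }
  set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(n * ensemble, sd = noise_ratio * sdx),
                  nrow = n, ncol = ensemble)
  raw <- .eemd_cpp(x, noise, as.integer(nsift), as.integer(max_imf))
  imfs <- raw[, seq_len(max_imf), drop = FALSE]
  residual <- raw[, max_imf + 1L]
  # fold negligible trailing modes into the residual
  etot <- sum(x^2)
  keep <- colSums(imfs^2) > 1e-10 * etot
  last <- if (any(keep)) max(which(keep)) else 0L
  if (last < max_imf) {
    residual <- residual + rowSums(imfs[, setdiff(seq_len(max_imf),
                                                  seq_len(last)), drop = FALSE])
    imfs <- imfs[, seq_len(last), drop = FALSE]
  }
  if (merge_ratio > 1 && ncol(imfs) > 1L)
    imfs <- merge_split_modes(imfs, fs, merge_ratio)
  colnames(imfs) <- if (ncol(imfs)) paste0("imf", seq_len(ncol(imfs)))
  out <- structure(list(imfs = imfs, residual = residual, fs = fs,
                        kind = kind, seed = seed),
                   class = "imf_set")
  an <- apply(imfs, 2, function(cj) hilbert_analytics(cj, fs), simplify = FALSE)
  out$amplitude <- vapply(an, `[[`, numeric(n), "amplitude")
  out$phase <- vapply(an, `[[`, numeric(n), "phase")
  out$freq <- vapply(an, `[[`, numeric(n), "freq")
  out
}

# Mean instantaneous frequency of one raw mode column (5 s edge trim).
mode_mean_freq <- function(cj, fs) {
  f <- hilbert_analytics(cj, fs)$freq
  k <- round(5 * fs); n <- length(f)
  if (n > 2 * k + 8) f <- f[(k + 1):(n - k)]
  mean(f)
}

# Sum adjacent averaged modes that carry the same rhythm (mean frequency
# ratio below `ratio`), iterating until no adjacent pair qualifies.
merge_split_modes <- function(imfs, fs, ratio) {
  repeat {
    k <- ncol(imfs)
    if (k < 2L) return(imfs)
    mf <- vapply(seq_len(k), function(j) {
      if (all(imfs[, j] == 0)) return(NA_real_)
      mode_mean_freq(imfs[, j], fs)
    }, 0)
    rr <- exp(abs(log(abs(mf[-k]) / pmax(abs(mf[-1]), 1e-12))))
    rr[!is.finite(rr)] <- Inf
    j <- which.min(rr)
    if (!length(j) || rr[j] >= ratio) return(imfs)
    imfs[, j] <- imfs[, j] + imfs[, j + 1L]
    imfs <- imfs[, -(j + 1L), drop = FALSE]
  }
}

#' @export
print.imf_set <- function(x, ...) {
  k <- ncol(x$imfs %||% matrix(nrow = 0, ncol = 0))
  cat(sprintf("<imf_set> %s: %d IMFs + residual (%d samples at %g Hz)\n",
              x$kind, k, length(x$residual), x$fs))
  if (k) {
    mf <- vapply(seq_len(k), function(j) mean_inst_freq(x, j), 0)
    cat("  mean instantaneous freq (Hz):",
        paste(sprintf("%.3f", mf), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.imf_set <- function(x, ...) {
  k <- ncol(x$imfs)
  op <- graphics::par(mfrow = c(k + 1, 1), mar = c(1.5, 4, 0.5, 1))
  on.exit(graphics::par(op))
  tt <- (seq_along(x$residual) - 1) / x$fs
  for (j in seq_len(k))
    plot(tt, x$imfs[, j], type = "l", ylab = paste0("IMF", j), xlab = "")
  plot(tt, x$residual, type = "l", ylab = "residual", xlab = "time (s)")
  invisible(x)
}

#' Hilbert analytics of a narrowband series
#'
#' Analytic signal `z = x + i * H(x)`; instantaneous amplitude `|z|`,
#' unwrapped instantaneous phase `arg(z)`, and instantaneous frequency
#' `(1/2pi) dphase/dt` by central differences (one-sided at the ends).
#'
#' @param x zero-mean narrowband numeric series (one IMF).
#' @param fs sampling rate, Hz.
#' @return list with `amplitude`, `phase` (rad, unwrapped), `freq` (Hz).
#' @export
hilbert_analytics <- function(x, fs) {
  if (inherits(x, "uniform_series")) { fs <- x$fs; x <- x$values }
  if (all(x == 0)) stop("all-zero input: instantaneous phase undefined",
                        call. = FALSE)
  z <- analytic_signal(x - mean(x))
  A <- Mod(z)
  phi <- unwrap_phase(Arg(z))
  n <- length(phi)
  f <- numeric(n)
  f[2:(n - 1)] <- (phi[3:n] - phi[1:(n - 2)]) * fs / (4 * pi)
  f[1] <- (phi[2] - phi[1]) * fs / (2 * pi)
  f[n] <- (phi[n] - phi[n - 1]) * fs / (2 * pi)
  list(amplitude = A, phase = phi, freq = f)
}

#' Mean instantaneous frequency of one IMF
#'
#' Mean of the instantaneous frequency after trimming `trim` seconds from
#' each end (Hilbert edge effects).
#'
#' @param imfset an `imf_set` from [eemd()].
#' @param j IMF index (1-based, fastest mode first).
#' @param trim seconds trimmed from each end (default 5).
#' @return mean frequency in Hz.
#' @export
mean_inst_freq <- function(imfset, j, trim = 5) {
  f <- imfset$freq[, j]
  k <- round(trim * imfset$fs)
  n <- length(f)
  if (n > 2 * k + 8) f <- f[(k + 1):(n - k)]
  mean(f)
}

#' Select the dominant (highest-energy) IMF
#'
#' Used on the respiration decomposition: the mode with the largest sum of
#' squares captures the primary respiratory oscillation. Ties break toward
#' the lower (faster) index.
#'
#' @param imfset an `imf_set` from [eemd()].
#' @return IMF index (1-based).
#' @export
select_dominant_imf <- function(imfset) {
  if (is.null(imfset$imfs) || ncol(imfset$imfs) < 1L)
    stop("imf_set has no IMFs", call. = FALSE)
  which.max(colSums(imfset$imfs^2))
}

#' Select the IMF whose mean frequency is closest to a target
#'
#' Used on the RRI/SBP/DBP decompositions to pick the respiration-matched
#' mode: argmin of `|mean instantaneous frequency - f_target|`, means taken
#' after a 5 s edge trim. Ties break toward the lower (faster) index.
#'
#' @param imfset an `imf_set` from [eemd()].
#' @param f_target target frequency, Hz (> 0).
#' @return IMF index (1-based).
#' @export
match_imf_by_frequency <- function(imfset, f_target) {
  if (f_target <= 0) stop("f_target must be positive", call. = FALSE)
  if (is.null(imfset$imfs) || ncol(imfset$imfs) < 1L)
    stop("imf_set has no IMFs", call. = FALSE)
  mf <- vapply(seq_len(ncol(imfset$imfs)),
               function(j) mean_inst_freq(imfset, j), 0)
  which.min(abs(mf - f_target))
}
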