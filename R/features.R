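#' Time-domain HRV metrics
#'
#' Mean R-R interval and SDNN (sample standard deviation, `ddof = 1`) of
#' the cleaned beat-by-beat intervals.
#'
#' @param beats cleaned [beat_series()] of kind `"RRI"`, or a numeric
#'   vector of intervals in ms.
#' @return named numeric vector `c(MeanRR, SDNN)` in ms.
#' @export
hrv_time <- function(beats) {
  v <- if (inherits(beats, "beat_series")) beats$values else as.numeric(beats)
  if (length(v) < 2L) stop("need at least 2 intervals", call. = FALSE)
  c(MeanRR = mean(v), SDNN = stats::sd(v))
}

#' Frequency-domain HRV metrics
#'
#' The cleaned R-R series is cubic-spline resampled at 4 Hz, linearly
#' detrended, and its power spectral density estimated by Welch-averaged
#' FFT (150 s Hann segments, 50% overlap; a single full-length segment when
#' the record is shorter). Band powers are integrated over the
#' low-frequency band LF = \[0.04, 0.15) Hz and high-frequency band
#' HF = \[0.15, 0.40) Hz; logs are natural.
#'
#' @param beats cleaned [beat_series()] of kind `"RRI"`.
#' @param resample_fs spectral resampling rate, Hz (default 4).
#' @param seg_len_s Welch segment length in seconds (default 150).
#' @param welch logical; `FALSE` gives a single full-length periodogram.
#' @return named vector `c(LF, HF, logLF, logHF, LF_HF)`; powers in ms^2.
#' @export
hrv_freq <- function(beats, resample_fs = 4, seg_len_s = 150, welch = TRUE) {
  stopifnot(inherits(beats, "beat_series"))
  span <- diff(range(beats$times))
  if (span < 120) stop("need at least 120 s of data", call. = FALSE)
  u <- resample_uniform(beats$times, beats$values, resample_fs, "RRI")
  y <- u$values
  tt <- seq_along(y)
  y <- stats::residuals(stats::lm(y ~ tt))      # linear detrend
  seg <- if (welch) round(seg_len_s * resample_fs) else length(y)
  ps <- welch_psd(y, resample_fs, seg_len = seg, overlap = 0.5)
  df <- ps$freq[2] - ps$freq[1]
  lf <- sum(ps$psd[ps$freq >= 0.04 & ps$freq < 0.15]) * df
  hf <- sum(ps$psd[ps$freq >= 0.15 & ps$freq < 0.40]) * df
  if (hf == 0) stop("HF power is zero: LF/HF undefined", call. = FALSE)
  c(LF = lf, HF = hf, logLF = log(lf), logHF = log(hf), LF_HF = lf / hf)
}

#' Segment a conditioned effort signal into breaths
#'
#' Zero-crossing segmentation with hysteresis: an inhale is a maximal run
#' of effort above `+h`, the following exhale a run below `-h`
#' (`h = 0.1` of the normalized amplitude); near-zero pauses are absorbed
#' into the preceding phase and runs shorter than 0.3 s are merged into
#' their neighbour. A breath spans one inhale onset to the next.
#'
#' @param effort conditioned [uniform_series()] (positive = inspiration),
#'   see [condition_rsp()].
#' @param h hysteresis threshold (default 0.1).
#' @param min_run_s minimum phase duration in seconds (default 0.3).
#' @return data.frame with one row per complete breath: `onset`, `in_end`
#'   (inhale end = exhale start), `next_onset` (s), and durations
#'   `inhale`, `exhale`, `duration` (s).
#' @export
segment_breaths <- function(effort, h = 0.1, min_run_s = 0.3) {
  stopifnot(inherits(effort, "uniform_series"))
  x <- effort$values; fs <- effort$fs
  state <- ifelse(x > h, 1L, ifelse(x < -h, -1L, 0L))
  # absorb pauses into the preceding phase
  for (i in seq_along(state)[-1])
    if (state[i] == 0L) state[i] <- state[i - 1L]
  # drop leading pause
  first <- which(state != 0L)[1]
  if (is.na(first)) stop("no breaths found in effort signal", call. = FALSE)
  state[seq_len(first - 1L)] <- state[first]
  # merge runs shorter than min_run_s into the previous phase
  r <- rle(state)
  min_len <- max(1L, round(min_run_s * fs))
  if (length(r$lengths) > 1L) {
    short <- which(r$lengths < min_len)
    for (s in short) if (s > 1L) r$values[s] <- r$values[s - 1L]
    state <- inverse.rle(r)
    r <- rle(state)
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  # inhale onsets = starts of +1 runs preceded by a -1 run (or record start)
  onsets_i <- starts[which(r$values == 1L &
                             c(-1L, head(r$values, -1L)) == -1L)]
  if (length(onsets_i) < 4L)
    stop("fewer than 3 complete breaths", call. = FALSE)
  t_of <- function(i) effort$t0 + (i - 1) / fs
  breaths <- data.frame(onset = numeric(0), in_end = numeric(0),
                        next_onset = numeric(0))
  for (k in seq_len(length(onsets_i) - 1L)) {
    a <- onsets_i[k]; b <- onsets_i[k + 1L]
    # inhale ends where state first turns -1 after a
    neg <- which(state[a:(b - 1L)] == -1L)
    if (length(neg) == 0L) next
    breaths <- rbind(breaths,
                     data.frame(onset = t_of(a),
                                in_end = t_of(a + neg[1] - 1L),
                                next_onset = t_of(b)))
  }
  if (nrow(breaths) < 3L)
    stop("fewer than 3 complete breaths", call. = FALSE)
  breaths$inhale <- breaths$in_end - breaths$onset
  breaths$exhale <- breaths$next_onset - breaths$in_end
  breaths$duration <- breaths$next_onset - breaths$onset
  breaths
}

#' Respiratory pattern metrics from a breath table
#'
#' Average inhale/exhale durations, breathing rate, and coefficients of
#' variation of the per-breath instantaneous rate and of the inhale/exhale
#' duty cycles. Duty cycles partition each breath into two phases (pauses
#' are absorbed during segmentation), so inhale duty + exhale duty = 1.
#'
#' @param breaths breath table from [segment_breaths()].
#' @return named vector `c(AED, AID, BR, BR_CV, EDC_CV, IDC_CV)`:
#'   durations in s, `BR` in Hz, CVs unitless (SD/mean, `ddof = 1`).
#' @export
resp_features <- function(breaths) {
  if (nrow(breaths) < 3L) stop("need at least 3 breaths", call. = FALSE)
  cv <- function(x) {
    m <- mean(x)
    if (m == 0) return(NA_real_)
    s <- stats::sd(x)
    if (s < 1e-12 * abs(m)) 0 else s / m   # guard against float dust
  }
  rate <- 1 / breaths$duration
  edc <- breaths$exhale / breaths$duration
  idc <- breaths$inhale / breaths$duration
  c(AED = mean(breaths$exhale), AID = mean(breaths$inhale),
    BR = 1 / mean(breaths$duration),
    BR_CV = cv(rate), EDC_CV = cv(edc), IDC_CV = cv(idc))
}

#' Hemodynamic summary (mean and standard error per channel)
#'
#' @param scalars named list of numeric vectors (e.g. the `scalars` slot of
#'   a [crv_record()], plus per-beat SBP/DBP values).
#' @return data.frame with columns `channel`, `mean`, `se` (SE = SD/sqrt(n);
#'   0 when n = 1); empty channels yield `NA` with a missing marker.
#' @export
hemo_summary <- function(scalars) {
  rows <- lapply(names(scalars), function(nm) {
    v <- scalars[[nm]]
    v <- v[is.finite(v)]
    if (length(v) == 0L)
      return(data.frame(channel = nm, mean = NA_real_, se = NA_real_,
                        missing = TRUE))
    se <- if (length(v) == 1L) 0 else stats::sd(v) / sqrt(length(v))
    data.frame(channel = nm, mean = mean(v), se = se, missing = FALSE)
  })
  do.call(rbind, rows)
}

#' Check that the breathing rate lies inside the HF band
#'
#' The HF band of the heart-rate spectrum (0.15-0.40 Hz) is fixed; records
#' whose breathing rate falls outside it are flagged because
#' respiration-driven vagal modulation would then leak out of HF.
#'
#' @param br breathing rate, Hz.
#' @param band HF band limits (default `c(0.15, 0.40)`).
#' @return logical: `TRUE` when the rate is inside the band.
#' @export
br_in_hf_band <- function(br, band = c(0.15, 0.40)) {
  is.finite(br) && br >= band[1] && br < band[2]
}
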