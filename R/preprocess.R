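#' Remove 50 Hz power-line interference
#'
#' Zero-phase second-order Butterworth band-stop filter centred on 50 Hz
#' (48-52 Hz stop band), applied forward-backward so the passband keeps
#' unit gain and zero phase shift.
#'
#' @param x numeric waveform.
#' @param fs sampling rate (Hz); must exceed 100 Hz so the notch sits below
#'   Nyquist.
#' @return filtered waveform, same length.
#' @export
notch_50hz <- function(x, fs) {
  check_waveform(x)
  if (fs <= 100)
    stop("fs must exceed 100 Hz for a 50 Hz notch", call. = FALSE)
  b <- signal::butter(2, c(48, 52) / (fs / 2), type = "stop")
  as.numeric(signal::filtfilt(b, x))
}

#' Condition the ECG channel
#'
#' Zero-phase 0.5-40 Hz Butterworth band-pass: removes baseline wander and
#' high-frequency noise while preserving QRS morphology.
#'
#' @inheritParams notch_50hz
#' @return filtered ECG.
#' @export
condition_ecg <- function(x, fs) {
  check_waveform(x)
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  b <- signal::butter(3, c(0.5, 40) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

#' Detect R peaks and build the raw R-R interval series
#'
#' Derivative-threshold detector: narrow band-pass (5-25 Hz), squared
#' derivative, 150 ms moving-window integration, adaptive threshold, 200 ms
#' refractory period. Peak instants are refined to the local ECG maximum
#' within +/- 100 ms of each detection.
#'
#' @param ecg conditioned ECG (see [condition_ecg()]).
#' @param fs sampling rate, Hz.
#' @return a [beat_series()] of kind `"RRI"`: `times` are the instants of
#'   beats 2..n, `values` the preceding R-R intervals in ms. The full R-peak
#'   time vector is attached as attribute `"peak_times"`.
#' @export
detect_r_peaks <- function(ecg, fs) {
  check_waveform(ecg, "ecg")
  if (diff(range(ecg)) == 0)
    stop("empty beat series: flatline ECG, no peaks found", call. = FALSE)
  b <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
  f <- as.numeric(signal::filtfilt(b, ecg))
  d <- c(0, diff(f)) * fs
  integ <- moving_average(d^2, max(3L, round(0.150 * fs)))
  thr <- 0.25 * stats::quantile(integ, 0.99, names = FALSE)
  if (thr <= 0)
    stop("empty beat series: no QRS energy above threshold", call. = FALSE)
  n <- length(integ)
  cand <- which(integ[2:(n - 1)] > integ[1:(n - 2)] &
                  integ[2:(n - 1)] >= integ[3:n] &
                  integ[2:(n - 1)] > thr) + 1L
  if (length(cand) == 0L)
    stop("empty beat series: no peaks found", call. = FALSE)
  # refractory: among candidates closer than 200 ms keep the strongest
  refr <- round(0.2 * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i); last <- i
    } else if (integ[i] > integ[keep[length(keep)]]) {
      keep[length(keep)] <- i; last <- i
    }
  }
  # refine to the ECG extremum within +/-100 ms
  half <- round(0.1 * fs)
  peaks <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(length(ecg), i + half)
    as.integer(lo + which.max(abs(ecg[lo:hi])) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) < 2L)
    stop("empty beat series: fewer than 2 beats detected", call. = FALSE)
  times <- (peaks - 1) / fs
  out <- beat_series(times[-1], diff(times) * 1000, kind = "RRI")
  attr(out, "peak_times") <- times
  out
}

#' Exclude ectopic and artifactual R-R intervals
#'
#' An interval is removed if it (1) exceeds 2000 ms, (2) falls below 300 ms,
#' (3) changes by more than 200 ms from the preceding retained interval, or
#' (4) deviates by more than 20% from the mean of the five most recent
#' retained intervals. Rules are evaluated in that order against intervals
#' already retained, so cleaning is idempotent; the first five retained
#' intervals are exempt from rule 4.
#'
#' @param beats a [beat_series()] of kind `"RRI"`.
#' @param max_removed_frac fraction of removals above which the result is
#'   flagged as a quality concern (default 0.2).
#' @return cleaned [beat_series()]; attributes `"n_removed"` (count) and
#'   `"quality_warning"` (logical).
#' @export
clean_rri <- function(beats, max_removed_frac = 0.2) {
  stopifnot(inherits(beats, "beat_series"))
  if (beats$kind != "RRI") stop("clean_rri expects kind = 'RRI'", call. = FALSE)
  v <- beats$values; t <- beats$times
  keep <- logical(length(v))
  kept <- numeric(0)
  for (i in seq_along(v)) {
    x <- v[i]
    drop <- x > 2000 || x < 300 ||
      (length(kept) >= 1L && abs(x - kept[length(kept)]) > 200) ||
      (length(kept) >= 5L &&
         abs(x - mean(tail(kept, 5))) > 0.2 * mean(tail(kept, 5)))
    if (!drop) {
      keep[i] <- TRUE
      kept <- c(kept, x)
    }
  }
  n_removed <- sum(!keep)
  out <- beat_series(t[keep], v[keep], kind = "RRI", cleaned = TRUE)
  attr(out, "n_removed") <- n_removed
  qw <- n_removed > max_removed_frac * length(v)
  if (qw)
    warning(sprintf("clean_rri removed %d of %d intervals (> %.0f%%): quality concern",
                    n_removed, length(v), 100 * max_removed_frac), call. = FALSE)
  attr(out, "quality_warning") <- qw
  out
}

#' Resample an event or sampled series onto a uniform grid
#'
#' Cubic-spline interpolation onto a grid at `target_fs`, spanning the
#' support `[first, last]` of the input times. Used at 8 Hz for the coupling
#' engine and at 4 Hz for HRV spectra.
#'
#' @param times strictly increasing support times (s); at least 4 points.
#' @param values values at the support times.
#' @param target_fs grid rate, Hz.
#' @param kind label carried into the output.
#' @return a [uniform_series()] with `t0` equal to the first support time.
#' @export
resample_uniform <- function(times, values, target_fs, kind = "series") {
  if (inherits(times, "beat_series")) {
    b <- times
    if (!missing(values) && is.numeric(values) && length(values) == 1L &&
        missing(target_fs)) { target_fs <- values }
    times <- b$times; values <- b$values; kind <- b$kind
  }
  if (length(times) < 4L)
    stop("resample_uniform needs at least 4 support points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("support times must be strictly increasing", call. = FALSE)
  grid <- seq(times[1], times[length(times)], by = 1 / target_fs)
  y <- stats::spline(times, values, xout = grid, method = "fmm")$y
  uniform_series(y, fs = target_fs, t0 = grid[1], kind = kind)
}

#' Condition the respiration channel into a normalized effort series
#'
#' Pipeline: cubic-spline resample to 8 Hz, first-order Butterworth
#' band-pass 0.01-2 Hz (zero-phase), first difference scaled by the sampling
#' rate (derivative), then robust min-max normalization to the open interval
#' (-1, 1) using the 1st-99th percentile range. A rising thoracic signal
#' (inspiration) maps to positive effort.
#'
#' @param rsp raw respiration waveform.
#' @param fs sampling rate of `rsp`, Hz.
#' @param target_fs output rate, Hz (default 8).
#' @return a [uniform_series()] of kind `"RSP"` with values strictly inside
#'   (-1, 1).
#' @export
condition_rsp <- function(rsp, fs, target_fs = 8) {
  check_waveform(rsp, "rsp")
  if (diff(range(rsp)) == 0)
    stop("constant respiration input: normalization degenerate", call. = FALSE)
  t_in <- (seq_along(rsp) - 1) / fs
  u <- if (abs(fs - target_fs) < 1e-9) {
    uniform_series(rsp, fs = target_fs, t0 = 0, kind = "RSP")
  } else {
    resample_uniform(t_in, rsp, target_fs, kind = "RSP")
  }
  b <- signal::butter(1, c(0.01, 2) / (target_fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(b, u$values))
  der <- c(filt[2] - filt[1], diff(filt)) * target_fs
  q <- stats::quantile(der, c(0.01, 0.99), names = FALSE)
  if (q[2] - q[1] <= 0)
    stop("constant respiration input: normalization degenerate", call. = FALSE)
  y <- 2 * (der - q[1]) / (q[2] - q[1]) - 1
  y <- pmin(pmax(y, -1), 1) * (1 - 1e-9)
  uniform_series(y, fs = target_fs, t0 = u$t0, kind = "RSP")
}

#' Condition the blood-pressure waveform and detect per-beat landmarks
#'
#' The waveform is band-pass filtered 0.5-12 Hz (zero-phase) for landmark
#' detection and smoothed with a 50 ms moving average for value read-out.
#' Each pulse contributes one peak (systolic, SBP) and one preceding onset
#' minimum (diastolic, DBP). Because the 0.5 Hz high-pass removes the
#' pressure baseline, landmark *positions* come from the filtered waveform
#' but SBP/DBP *values* are read from the smoothed, baseline-preserving
#' waveform at the detected instants.
#'
#' @param cbp raw continuous blood-pressure waveform (mmHg).
#' @param fs sampling rate, Hz.
#' @return list with elements `sbp` and `dbp`, each a [beat_series()].
#' @export
condition_cbp_and_detect_beats <- function(cbp, fs) {
  check_waveform(cbp, "cbp")
  if (diff(range(cbp)) == 0)
    stop("empty beat series: constant pressure input", call. = FALSE)
  b <- signal::butter(2, c(0.5, 12) / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(b, cbp))
  smooth <- moving_average(cbp, max(3L, round(0.050 * fs)))
  thr <- 0.3 * stats::quantile(filt, 0.99, names = FALSE)
  if (thr <= 0)
    stop("empty beat series: no pulsatile component detected", call. = FALSE)
  n <- length(filt)
  cand <- which(filt[2:(n - 1)] > filt[1:(n - 2)] &
                  filt[2:(n - 1)] >= filt[3:n] &
                  filt[2:(n - 1)] > thr) + 1L
  if (length(cand) == 0L)
    stop("empty beat series: no pulses detected", call. = FALSE)
  refr <- round(0.3 * fs)
  peaks <- integer(0); last <- -Inf
  for (i in cand) {
    if (i - last >= refr) { peaks <- c(peaks, i); last <- i }
    else if (filt[i] > filt[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i; last <- i
    }
  }
  if (length(peaks) < 2L)
    stop("empty beat series: fewer than 2 pulses detected", call. = FALSE)
  ibi <- stats::median(diff(peaks))
  onsets <- vapply(peaks, function(p) {
    lo <- max(1L, as.integer(p - round(0.6 * ibi)))
    as.integer(lo + which.min(filt[lo:p]) - 1L)
  }, integer(1))
  # value read-out on the smoothed absolute waveform
  sbp_t <- (peaks - 1) / fs
  dbp_t <- (onsets - 1) / fs
  ok <- !duplicated(dbp_t)
  list(sbp = beat_series(sbp_t, smooth[peaks], kind = "SBP"),
       dbp = beat_series(dbp_t[ok], smooth[onsets][ok], kind = "DBP"))
}

#' Preprocess a multimodal record into the four coupling-ready series
#'
#' Applies the full conditioning chain: 50 Hz notch on all channels, ECG
#' band-pass + R-peak detection + R-R cleaning, respiration conditioning,
#' pressure landmark detection, and cubic-spline resampling of RRI/SBP/DBP
#' to a common 8 Hz rate. All four series are then trimmed to their common
#' overlapping time span on a shared grid.
#'
#' @param record a [crv_record()].
#' @param target_fs common output rate, Hz (default 8).
#' @param apply_notch apply the 50 Hz notch first (disable for synthetic
#'   records with no line interference; default TRUE).
#' @return list of class `crv_prep` with [uniform_series()] elements
#'   `rsp`, `rri`, `sbp`, `dbp`, the cleaned [beat_series()] `rri_beats`,
#'   `sbp_beats`, `dbp_beats`, and the shared rate `fs`.
#' @export
preprocess_record <- function(record, target_fs = 8, apply_notch = TRUE) {
  stopifnot(inherits(record, "crv_record"))
  ecg <- record$ecg; rsp <- record$rsp; cbp <- record$cbp
  if (apply_notch && record$fs > 100) {
    ecg <- notch_50hz(ecg, record$fs)
    rsp <- notch_50hz(rsp, record$fs)
    cbp <- notch_50hz(cbp, record$fs)
  }
  ecg <- condition_ecg(ecg, record$fs)
  rri_raw <- detect_r_peaks(ecg, record$fs)
  rri_beats <- clean_rri(rri_raw)
  press <- condition_cbp_and_detect_beats(cbp, record$fs)
  rsp_u <- condition_rsp(rsp, record$fs, target_fs)
  rri_u <- resample_uniform(rri_beats$times, rri_beats$values, target_fs, "RRI")
  sbp_u <- resample_uniform(press$sbp$times, press$sbp$values, target_fs, "SBP")
  dbp_u <- resample_uniform(press$dbp$times, press$dbp$values, target_fs, "DBP")
  # common overlapping span on a shared grid
  t0 <- max(rsp_u$t0, rri_u$t0, sbp_u$t0, dbp_u$t0)
  t1 <- min(vapply(list(rsp_u, rri_u, sbp_u, dbp_u),
                   function(u) u$t0 + (length(u$values) - 1) / u$fs, 0))
  if (t1 - t0 < 60)
    stop("common span of preprocessed series is shorter than 60 s", call. = FALSE)
  grid <- seq(ceiling(t0 * target_fs) / target_fs, t1, by = 1 / target_fs)
  regrid <- function(u) {
    y <- stats::spline(series_times(u), u$values, xout = grid, method = "fmm")$y
    uniform_series(y, fs = target_fs, t0 = grid[1], kind = u$kind)
  }
  structure(list(rsp = regrid(rsp_u), rri = regrid(rri_u),
                 sbp = regrid(sbp_u), dbp = regrid(dbp_u),
                 rri_beats = rri_beats, sbp_beats = press$sbp,
                 dbp_beats = press$dbp, fs = target_fs),
            class = "crv_prep")
}

#' @export
print.crv_prep <- function(x, ...) {
  cat("<crv_prep> four series at", x$fs, "Hz,",
      length(x$rsp$values), "samples each;",
      length(x$rri_beats$times), "cleaned beats\n")
  invisible(x)
}
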