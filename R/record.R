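#' Multimodal physiological record
#'
#' Container for one subject's synchronous raw waveforms (ECG, respiratory
#' effort, continuous blood pressure), per-record scalar channels and
#' metadata. All waveform channels must share the sampling rate `fs` and
#' have equal length.
#'
#' @param ecg numeric, single-lead ECG (mV).
#' @param rsp numeric, thoracic respiratory effort (arbitrary units).
#' @param cbp numeric, continuous blood-pressure waveform (mmHg).
#' @param fs common sampling rate in Hz.
#' @param scalars named list of per-record scalar channels, each a numeric
#'   vector: `SpO2` (%), `MAP` (mmHg), `CO` (L/min), `PPV` (%). Consumed as
#'   device channels, never re-derived from the waveforms.
#' @param subject_id character scalar.
#' @param group_label group membership label (e.g. `"HA0"`..`"HA4"`).
#' @param truth optional ground-truth list (synthetic records only).
#' @return object of class `crv_record`.
#' @export
#' @examples
#' rec <- simulate_record(crv_params(duration = 150, seed = 1))
#' rec
crv_record <- function(ecg, rsp, cbp, fs,
                       scalars = list(), subject_id = "S1",
                       group_label = NA_character_, truth = NULL) {
  check_waveform(ecg, "ecg"); check_waveform(rsp, "rsp")
  check_waveform(cbp, "cbp")
  if (length(unique(c(length(ecg), length(rsp), length(cbp)))) != 1L)
    stop("all waveform channels must have equal length", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)", call. = FALSE)
  duration <- length(ecg) / fs
  if (duration < 120)
    stop("record must be at least 120 s for windowed coupling analysis",
         call. = FALSE)
  structure(list(ecg = ecg, rsp = rsp, cbp = cbp, fs = fs,
                 scalars = scalars, subject_id = subject_id,
                 group_label = group_label, duration = duration,
                 truth = truth),
            class = "crv_record")
}

#' @export
print.crv_record <- function(x, ...) {
  cat("<crv_record>", x$subject_id,
      if (!is.na(x$group_label)) paste0("[", x$group_label, "]"), "\n")
  cat(sprintf("  %.1f s at %g Hz (%d samples/channel)\n",
              x$duration, x$fs, length(x$ecg)))
  if (length(x$scalars))
    cat("  scalar channels:", paste(names(x$scalars), collapse = ", "), "\n")
  if (!is.null(x$truth)) cat("  ground truth attached (synthetic record)\n")
  invisible(x)
}

#' Event (beat-by-beat) series
#'
#' Times are event instants in seconds (strictly increasing); values are the
#' per-event quantity: R-R intervals in ms (`kind = "RRI"`) or pressures in
#' mmHg (`"SBP"`, `"DBP"`).
#'
#' @param times numeric, strictly increasing event times (s).
#' @param values numeric, one value per event.
#' @param kind one of `"RRI"`, `"SBP"`, `"DBP"`.
#' @param cleaned logical flag: has artifact exclusion been applied?
#' @return object of class `beat_series`.
#' @export
beat_series <- function(times, values, kind = c("RRI", "SBP", "DBP"),
                        cleaned = FALSE) {
  kind <- match.arg(kind)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(times) == 0L)
    stop("empty beat series (no events detected)", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind, cleaned = cleaned),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %s: %d events over %.1f s%s\n", x$kind,
              length(x$times), diff(range(x$times)),
              if (isTRUE(x$cleaned)) " (cleaned)" else ""))
  invisible(x)
}

#' Uniformly sampled series
#'
#' @param values numeric samples (no missing values).
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample, s.
#' @param kind label (e.g. `"RSP"`, `"RRI"`, `"SBP"`, `"DBP"`).
#' @return object of class `uniform_series`.
#' @export
uniform_series <- function(values, fs, t0 = 0, kind = "series") {
  if (any(!is.finite(values)))
    stop("uniform series must not contain missing values", call. = FALSE)
  structure(list(values = as.numeric(values), fs = fs, t0 = t0, kind = kind),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %s: %d samples at %g Hz from t0 = %.3f s\n",
              x$kind, length(x$values), x$fs, x$t0))
  invisible(x)
}

# Sample times of a uniform series.
series_times <- function(u) u$t0 + (seq_along(u$values) - 1) / u$fs

#' Read a multimodal record from per-channel CSV files
#'
#' Each waveform file must have columns `time_s` and `value`; all waveform
#' channels must share a common, constant sampling interval. Scalar-channel
#' files use the same layout and may be sampled arbitrarily.
#'
#' @param ecg_file,rsp_file,cbp_file paths to waveform CSVs.
#' @param scalar_files named character vector of paths for scalar channels
#'   (names become channel names, e.g. `c(SpO2 = "spo2.csv")`).
#' @param subject_id,group_label metadata, see [crv_record()].
#' @return a [crv_record()].
#' @export
read_record_csv <- function(ecg_file, rsp_file, cbp_file,
                            scalar_files = character(),
                            subject_id = "S1", group_label = NA_character_) {
  read_chan <- function(f) {
    d <- utils::read.csv(f)
    if (!all(c("time_s", "value") %in% names(d)))
      stop("channel CSV must have columns time_s, value: ", f, call. = FALSE)
    d
  }
  e <- read_chan(ecg_file); r <- read_chan(rsp_file); c <- read_chan(cbp_file)
  dt <- diff(e$time_s)
  if (max(abs(dt - dt[1])) > 1e-6)
    stop("ECG channel is not uniformly sampled", call. = FALSE)
  fs <- 1 / dt[1]
  scalars <- lapply(scalar_files, function(f) read_chan(f)$value)
  names(scalars) <- names(scalar_files)
  crv_record(e$value, r$value, c$value, fs = fs, scalars = scalars,
             subject_id = subject_id, group_label = group_label)
}

#' Write cleaned series to a tidy CSV
#'
#' One row per sample/event: `subject_id, kind, t, value`.
#'
#' @param series a list of [uniform_series()] and/or [beat_series()].
#' @param file output path.
#' @param subject_id subject identifier written to every row.
#' @return the file path, invisibly.
#' @export
write_series_csv <- function(series, file, subject_id = "S1") {
  rows <- lapply(series, function(s) {
    if (inherits(s, "uniform_series"))
      data.frame(subject_id = subject_id, kind = s$kind,
                 t = series_times(s), value = s$values)
    else
      data.frame(subject_id = subject_id, kind = s$kind,
                 t = s$times, value = s$values)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
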