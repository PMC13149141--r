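#' Sliding-window phase synchronization index
#'
#' For two unwrapped instantaneous phase series on the same grid, the
#' 1:1 phase difference `dphi = phi1 - phi2` is summarized in sliding
#' windows of length `T` (stepped by `step`): within each window centred at
#' `t_i`, `rho_i = |mean(exp(1i * dphi))|` over the closed sample interval
#' `[t_i - T/2, t_i + T/2]`. Values lie in `[0, 1]`: 1 means perfect
#' locking, 0 uniform phase scatter.
#'
#' @param phi1,phi2 unwrapped phase series (rad), equal length.
#' @param fs sampling rate, Hz (default 8).
#' @param T window length, s (default 50).
#' @param step window step, s (default 1).
#' @param pair label for the signal pair (e.g. `"RSP-RRI"`).
#' @return object of class `sync_series`: list with `rho`, window `centers`
#'   (s, relative to the start of the series), `T`, `step`, `pair`.
#' @export
phase_sync_series <- function(phi1, phi2, fs = 8, T = 50, step = 1,
                              pair = "pair") {
  if (length(phi1) != length(phi2))
    stop("phase series must have equal length", call. = FALSE)
  n <- length(phi1)
  win <- round(T * fs)           # samples spanning [t - T/2, t + T/2]
  if (n < win + 1L)
    stop("series shorter than one window", call. = FALSE)
  dphi <- phi1 - phi2
  ph <- exp(1i * dphi)
  cs <- cumsum(ph)
  half <- win / 2
  centers_idx <- seq(1 + ceiling(half), n - floor(half), by = round(step * fs))
  lo <- centers_idx - floor(half)
  hi <- centers_idx + floor(half)
  sums <- cs[hi] - c(0, cs)[lo]
  rho <- Mod(sums) / (hi - lo + 1)
  structure(list(rho = as.numeric(rho),
                 centers = (centers_idx - 1) / fs,
                 T = T, step = step, fs = fs, pair = pair),
            class = "sync_series")
}

#' @export
print.sync_series <- function(x, ...) {
  cat(sprintf("<sync_series> %s: %d windows (T = %g s, step = %g s), mean rho = %.3f\n",
              x$pair, length(x$rho), x$T, x$step, mean(x$rho)))
  invisible(x)
}

#' @export
plot.sync_series <- function(x, ...) {
  plot(x$centers, x$rho, type = "l", ylim = c(0, 1),
       xlab = "window center (s)", ylab = expression(rho),
       main = x$pair, ...)
  invisible(x)
}

# Composite total from the five pairwise values.
# grouping "primary": rr + (rs + rd)/2 + (sr + dr)/2  (respiratory-cardiac
# pair undivided, the two vascular groups averaged); "naive": the flat
# reading (rr + rs + rd)/2 + (sr + dr)/2.
composite_total <- function(rsp_rri, rsp_sbp, rsp_dbp, sbp_rri, dbp_rri,
                            grouping = c("primary", "naive")) {
  grouping <- match.arg(grouping)
  if (grouping == "primary")
    rsp_rri + (rsp_sbp + rsp_dbp) / 2 + (sbp_rri + dbp_rri) / 2
  else
    (rsp_rri + rsp_sbp + rsp_dbp) / 2 + (sbp_rri + dbp_rri) / 2
}

#' Total coupling strength / complexity from pairwise values
#'
#' Combines the five pairwise coupling metrics into the composite total:
#' `total = x_RSP-RRI + (x_RSP-SBP + x_RSP-DBP)/2 + (x_SBP-RRI + x_DBP-RRI)/2`.
#' The cardio-respiratory pair enters whole; the two respiratory-vascular
#' and the two cardio-vascular pairs are each averaged. An alternative flat
#' grouping (`"naive"`: first three averaged over 2 as well) is provided
#' for comparison but is inconsistent with published composite values.
#'
#' @param pairwise named numeric vector with elements `RSP-RRI`, `RSP-SBP`,
#'   `RSP-DBP`, `SBP-RRI`, `DBP-RRI` (or a plain length-5 vector in that
#'   order).
#' @param grouping `"primary"` (default) or `"naive"`.
#' @return the composite total (scalar).
#' @export
#' @examples
#' coupling_total(c(0.78, 0.48, 0.53, 0.48, 0.56))   # 1.805
coupling_total <- function(pairwise, grouping = c("primary", "naive")) {
  nm <- c("RSP-RRI", "RSP-SBP", "RSP-DBP", "SBP-RRI", "DBP-RRI")
  if (!is.null(names(pairwise)) && all(nm %in% names(pairwise)))
    pairwise <- pairwise[nm]
  stopifnot(length(pairwise) == 5L)
  unname(composite_total(pairwise[1], pairwise[2], pairwise[3], pairwise[4],
                         pairwise[5], grouping = match.arg(grouping)))
}

#' Multimodal coupling profile of four preprocessed series
#'
#' Runs the full coupling engine on the 8 Hz respiration, R-R interval,
#' systolic and diastolic pressure series sharing one grid:
#'
#' 1. EEMD of each series ([eemd()]).
#' 2. Dominant (highest-energy) respiration IMF; frequency-matched IMF of
#'    each other series ([select_dominant_imf()],
#'    [match_imf_by_frequency()]).
#' 3. Sliding-window phase synchronization for the five pairs
#'    RSP-RRI, RSP-SBP, RSP-DBP, SBP-RRI, DBP-RRI ([phase_sync_series()]).
#' 4. Strength = time-mean of each synchronization series; complexity =
#'    multiscale entropy of each series reduced to a scalar ([rcmse()],
#'    [complexity_index()]); composite totals via [coupling_total()].
#'
#' @param rsp,rri,sbp,dbp [uniform_series()] at a common rate on a common
#'   span (as produced by [preprocess_record()]).
#' @param noise_ratio,ensemble,seed EEMD parameters, see [eemd()].
#' @param T,step synchronization window length and step (s), see
#'   [phase_sync_series()].
#' @param m,r_fraction,scales multiscale-entropy parameters, see [rcmse()].
#' @param grouping composite grouping, see [coupling_total()].
#' @return object of class `coupling_profile`: named numeric vectors
#'   `strength` and `complexity` (five pairs each), scalars `rho_total` and
#'   `C_total`, the five `sync` series, per-pair `rcmse` vectors, the
#'   selected IMF indices, and the parameter set.
#' @export
coupling_profile <- function(rsp, rri, sbp, dbp,
                             noise_ratio = 0.2, ensemble = 100, seed = 1L,
                             T = 50, step = 1,
                             m = 2L, r_fraction = 0.15, scales = 1:3,
                             grouping = c("primary", "naive")) {
  grouping <- match.arg(grouping)
  series <- list(RSP = rsp, RRI = rri, SBP = sbp, DBP = dbp)
  stopifnot(all(vapply(series, inherits, TRUE, "uniform_series")))
  len <- vapply(series, function(u) length(u$values), 0L)
  if (length(unique(len)) != 1L)
    stop("series must share one grid (equal lengths)", call. = FALSE)
  fs <- rsp$fs
  # EEMD per series; seeds offset per channel so noise draws are independent
  sets <- mapply(function(u, off) eemd(u, noise_ratio = noise_ratio,
                                       ensemble = ensemble,
                                       seed = as.integer(seed) + off),
                 series, 0:3, SIMPLIFY = FALSE)
  dom <- select_dominant_imf(sets$RSP)
  f_resp <- mean_inst_freq(sets$RSP, dom)
  idx <- c(RSP = dom,
           RRI = match_imf_by_frequency(sets$RRI, f_resp),
           SBP = match_imf_by_frequency(sets$SBP, f_resp),
           DBP = match_imf_by_frequency(sets$DBP, f_resp))
  phase <- mapply(function(s, j) s$phase[, j], sets, idx, SIMPLIFY = FALSE)
  pairs <- list(`RSP-RRI` = c("RSP", "RRI"), `RSP-SBP` = c("RSP", "SBP"),
                `RSP-DBP` = c("RSP", "DBP"), `SBP-RRI` = c("SBP", "RRI"),
                `DBP-RRI` = c("DBP", "RRI"))
  sync <- lapply(names(pairs), function(p) {
    ab <- pairs[[p]]
    phase_sync_series(phase[[ab[1]]], phase[[ab[2]]], fs = fs,
                      T = T, step = step, pair = p)
  })
  names(sync) <- names(pairs)
  strength <- vapply(sync, function(s) mean(s$rho), 0)
  ent <- lapply(sync, function(s) rcmse(s$rho, m = m,
                                        r_fraction = r_fraction,
                                        scales = scales))
  complexity <- vapply(ent, complexity_index, 0)
  structure(list(strength = strength, complexity = complexity,
                 rho_total = unname(coupling_total(strength, grouping)),
                 C_total = unname(coupling_total(complexity, grouping)),
                 sync = sync, rcmse = ent, imf_index = idx,
                 f_resp = f_resp,
                 params = list(noise_ratio = noise_ratio, ensemble = ensemble,
                               seed = seed, T = T, step = step, m = m,
                               r_fraction = r_fraction, scales = scales,
                               grouping = grouping)),
            class = "coupling_profile")
}

#' @export
print.coupling_profile <- function(x, digits = 3, ...) {
  cat("<coupling_profile>\n")
  cat("  dominant respiration frequency:",
      sprintf("%.3f Hz", x$f_resp), "\n")
  m <- rbind(strength = x$strength, complexity = x$complexity)
  print(round(m, digits))
  cat(sprintf("  rho_total = %.3f   C_total = %.3f   (grouping: %s)\n",
              x$rho_total, x$C_total, x$params$grouping))
  invisible(x)
}

#' @export
summary.coupling_profile <- function(object, ...) {
  out <- c(object$strength, rho_total = object$rho_total,
           stats::setNames(object$complexity,
                           paste0("C_", names(object$complexity))),
           C_total = object$C_total)
  out
}

#' @export
plot.coupling_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(5, 1), mar = c(2, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (p in names(x$sync)) plot(x$sync[[p]])
  invisible(x)
}

#' Write a coupling profile to JSON / its sync series to CSV
#'
#' @param profile a [coupling_profile()].
#' @param json_file path for the scalar profile (JSON); `NULL` to skip.
#' @param csv_file path for the synchronization series (CSV with columns
#'   `pair, t, rho`); `NULL` to skip.
#' @return invisibly, the profile.
#' @export
write_profile <- function(profile, json_file = NULL, csv_file = NULL) {
  if (!is.null(json_file)) {
    obj <- list(strength = as.list(profile$strength),
                complexity = as.list(profile$complexity),
                rho_total = profile$rho_total, C_total = profile$C_total,
                f_resp = profile$f_resp, params = profile$params)
    jsonlite::write_json(obj, json_file, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_file)) {
    rows <- do.call(rbind, lapply(profile$sync, function(s)
      data.frame(pair = s$pair, t = s$centers, rho = s$rho)))
    utils::write.csv(rows, csv_file, row.names = FALSE)
  }
  invisible(profile)
}
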