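#' Generator parameters for synthetic multimodal records
#'
#' Defines the physiological structure the analysis assumes: a respiratory
#' phase oscillator with per-cycle timing jitter, an integrate-and-fire
#' (IPFM) heartbeat model whose instantaneous R-R interval is modulated by
#' respiration (RSA) and by a 0.1 Hz low-frequency rhythm, and per-beat
#' pressures modulated by respiratory pumping and a 0.1 Hz Mayer wave.
#' The coupling-jitter parameter `coupling_jitter` (rad) injects slow phase
#' noise between respiration and the RSA/pressure modulations, degrading
#' phase locking without changing marginal amplitudes.
#'
#' @param duration record length, s (default 300, a 5-minute record).
#' @param fs_out waveform sampling rate, Hz (default 250).
#' @param f_resp mean breathing rate, Hz (default 0.25).
#' @param resp_jitter SD of the Gaussian respiratory phase increment per
#'   cycle (unitless; 0 = metronomic breathing).
#' @param hr0 baseline heart rate, bpm (default 60).
#' @param rsa_gain respiratory modulation depth of the R-R interval, ms.
#' @param lf_gain 0.1 Hz modulation depth of the R-R interval, ms.
#' @param hrv_noise_gain SD (ms) of the broadband (vagally mediated)
#'   R-R variability, modelled as an Ornstein-Uhlenbeck process with a
#'   0.2 s correlation time (uncorrelated from beat to beat). Drives the irregularity (sample entropy) of
#'   the beat-to-beat series.
#' @param coupling_jitter SD (rad) of the slow phase noise between
#'   respiration and the cardiac/vascular modulations.
#' @param regime_switch `NULL` (off) or `list(period, depth)`: alternating
#'   epochs of length `period` s in which the coupling jitter is increased
#'   by `depth` rad, producing high/low-coupling regimes.
#' @param sbp0,dbp0 baseline systolic/diastolic pressure, mmHg.
#' @param resp_pump_gain respiratory modulation of SBP, mmHg.
#' @param mayer_gain 0.1 Hz Mayer-wave modulation of SBP, mmHg.
#' @param pressure_delay respiration-to-pressure transport delay, s.
#' @param ecg_noise_sd,rsp_noise_sd,cbp_noise_sd additive measurement-noise
#'   SDs (mV, fraction of effort amplitude, mmHg).
#' @param bp_beat_noise_sd per-beat SBP/DBP noise SD, mmHg.
#' @param spo2,map0,co,ppv scalar-channel preset means (%; mmHg; L/min; %).
#' @param seed integer seed.
#' @return list of class `crv_params`.
#' @export
crv_params <- function(duration = 300, fs_out = 250,
                       f_resp = 0.25, resp_jitter = 0.05,
                       hr0 = 60, rsa_gain = 50, lf_gain = 25,
                       hrv_noise_gain = 15,
                       coupling_jitter = 0, regime_switch = NULL,
                       sbp0 = 115, dbp0 = 70,
                       resp_pump_gain = 4, mayer_gain = 2,
                       pressure_delay = 0.2,
                       ecg_noise_sd = 0.01, rsp_noise_sd = 0.01,
                       cbp_noise_sd = 0.3, bp_beat_noise_sd = 0.5,
                       spo2 = 96.8, map0 = NULL, co = 5, ppv = 5,
                       seed = 1L) {
  stopifnot(f_resp > 0.1, f_resp < 0.5, hr0 > 40, hr0 < 180,
            rsa_gain >= 0, lf_gain >= 0, coupling_jitter >= 0,
            resp_jitter >= 0, resp_pump_gain >= 0, mayer_gain >= 0)
  if (is.null(map0)) map0 <- dbp0 + (sbp0 - dbp0) / 3
  structure(as.list(environment()), class = "crv_params")
}

# Ornstein-Uhlenbeck phase-noise process, unit stationary SD,
# correlation time tau_c seconds.
ou_process <- function(n, dt, tau_c = 10) {
  a <- exp(-dt / tau_c)
  b <- sqrt(1 - a^2)
  e <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- e[1]
  for (i in 2:n) x[i] <- a * x[i - 1] + b * e[i]
  x
}

#' Generate the respiratory phase, effort and thoracic waveform
#'
#' The respiratory phase advances at `2*pi*f_resp` with Gaussian per-cycle
#' increments of SD `resp_jitter`; effort is `sin(theta)` and the emitted
#' thoracic waveform is `-cos(theta)` (rising during inspiration), so that
#' the conditioning derivative recovers the effort. Breath onsets (ground
#' truth) are the up-crossings of phase through multiples of `2*pi`.
#'
#' @param params a [crv_params()]. Uses the current RNG state; seed before
#'   calling (done by [simulate_record()]).
#' @return list: `wave` (thoracic waveform with measurement noise),
#'   `effort` (noise-free `sin(theta)`), `theta` (phase, rad), `t` (s),
#'   `onsets` (truth breath-onset times, s).
#' @export
gen_respiration <- function(params) {
  dt <- 1 / params$fs_out
  n <- round(params$duration * params$fs_out)
  t <- (seq_len(n) - 1) * dt
  # instantaneous breathing frequency wanders around f_resp: an OU process
  # with correlation time of half a breath scales the rate by
  # (1 + resp_jitter * zeta), giving per-cycle phase-walk SD ~ resp_jitter
  # cycles while keeping the phase monotone.
  f_inst <- if (params$resp_jitter > 0) {
    zeta <- ou_process(n, dt, tau_c = 0.5 / params$f_resp)
    pmax(params$f_resp * (1 + params$resp_jitter * zeta), 0.2 * params$f_resp)
  } else rep(params$f_resp, n)
  theta <- cumsum(2 * pi * f_inst * dt) - 2 * pi * f_inst[1] * dt
  cross <- which(diff(floor(theta / (2 * pi))) >= 1)
  onsets <- vapply(cross, function(i) {
    lev <- 2 * pi * floor(theta[i + 1] / (2 * pi))
    t[i] + dt * (lev - theta[i]) / (theta[i + 1] - theta[i])
  }, 0)
  effort <- sin(theta)
  wave <- -cos(theta) + stats::rnorm(n, sd = params$rsp_noise_sd)
  list(wave = wave, effort = effort, theta = theta, t = t, onsets = onsets)
}

# Effective coupling-jitter SD over time (regime switching doubles up the
# base jitter by `depth` in alternating epochs).
sigma_profile <- function(params, t) {
  s <- rep(params$coupling_jitter, length(t))
  rs <- params$regime_switch
  if (!is.null(rs))
    s <- s + rs$depth * (floor(t / rs$period) %% 2)
  s
}

#' Generate heartbeats by integral pulse frequency modulation
#'
#' The instantaneous R-R interval is
#' `RR(t) = RR0 * (1 + a*sin(theta_r + sigma*eta(t)) + b*sin(2*pi*0.1*t + phi0))`
#' with `a = rsa_gain/RR0`, `b = lf_gain/RR0` (gains in ms) and `eta` a
#' unit-variance Ornstein-Uhlenbeck process; a beat fires whenever the
#' integral of `1/RR(t)` gains one unit. The ECG is rendered as canonical
#' Q-R-T template pulses at the beat times.
#'
#' @param resp output of [gen_respiration()].
#' @param params a [crv_params()].
#' @return list: `beat_times` (s), `rri_ms` (truth intervals), `ecg`
#'   (waveform, mV), `rr_inst` (instantaneous R-R, s, on the grid).
#' @export
gen_heartbeats_ipfm <- function(resp, params) {
  t <- resp$t; dt <- t[2] - t[1]; n <- length(t)
  rr0 <- 60 / params$hr0                    # s
  a <- params$rsa_gain / 1000 / rr0
  b <- params$lf_gain / 1000 / rr0
  sig <- sigma_profile(params, t)
  eta <- if (any(sig > 0)) ou_process(n, dt) else numeric(n)
  phi0 <- stats::runif(1, 0, 2 * pi)
  broad <- if (params$hrv_noise_gain > 0)
    params$hrv_noise_gain / 1000 * ou_process(n, dt, tau_c = 0.2)
  else numeric(n)
  rr <- rr0 * (1 + a * sin(resp$theta + sig * eta) +
                 b * sin(2 * pi * 0.1 * t + phi0)) + broad
  if (any(rr <= 0.25))
    stop("parameter error: instantaneous R-R interval <= 250 ms", call. = FALSE)
  integ <- cumsum(dt / rr)
  k <- floor(integ)
  cross <- which(diff(k) >= 1)
  beat_times <- vapply(cross, function(i) {
    lev <- k[i + 1]
    t[i] + dt * (lev - integ[i]) / (integ[i + 1] - integ[i])
  }, 0)
  if (length(beat_times) < 3L)
    stop("parameter error: too few beats generated", call. = FALSE)
  ecg <- numeric(n)
  add_bump <- function(center, amp, width) {
    lo <- max(1L, floor((center - 4 * width) / dt) + 1L)
    hi <- min(n, ceiling((center + 4 * width) / dt) + 1L)
    if (lo > hi) return(invisible())
    idx <- lo:hi
    ecg[idx] <<- ecg[idx] + amp * exp(-((t[idx] - center)^2) / (2 * width^2))
  }
  for (tb in beat_times) {
    add_bump(tb - 0.030, -0.12, 0.010)   # Q
    add_bump(tb, 1.0, 0.012)             # R
    add_bump(tb + 0.060, -0.18, 0.012)   # S
    add_bump(tb + 0.250, 0.22, 0.045)    # T
  }
  if (params$ecg_noise_sd > 0)
    ecg <- ecg + stats::rnorm(n, sd = params$ecg_noise_sd)
  list(beat_times = beat_times, rri_ms = diff(beat_times) * 1000,
       ecg = ecg, rr_inst = rr)
}

#' Generate the continuous pressure waveform and per-beat truth
#'
#' Per-beat systolic pressure is
#' `SBP_k = sbp0 + resp_pump_gain * sin(theta_r(t_k - delay) + sigma*eta2)
#'  + mayer_gain * sin(2*pi*0.1*t_k) + noise`; diastolic values use half
#' the modulation gains around `dbp0`. The waveform is rendered as one
#' pulse template per beat: onset at the beat time with value `DBP_k`,
#' rising to `SBP_k` and decaying back within the beat.
#'
#' @param beats output of [gen_heartbeats_ipfm()].
#' @param resp output of [gen_respiration()].
#' @param params a [crv_params()].
#' @return list: `cbp` (waveform, mmHg), `sbp`, `dbp` (per-beat truth),
#'   `beat_times` (s).
#' @export
gen_pressure <- function(beats, resp, params) {
  t <- resp$t; dt <- t[2] - t[1]; n <- length(t)
  tb <- beats$beat_times
  sig <- sigma_profile(params, tb)
  eta2 <- if (any(sig > 0)) ou_process(length(tb), mean(diff(tb))) else
    numeric(length(tb))
  theta_at <- stats::approx(t, resp$theta, xout = pmax(tb - params$pressure_delay, 0),
                            rule = 2)$y
  mod <- sin(theta_at + sig * eta2)
  mayer <- sin(2 * pi * 0.1 * tb)
  sbp <- params$sbp0 + params$resp_pump_gain * mod +
    params$mayer_gain * mayer +
    stats::rnorm(length(tb), sd = params$bp_beat_noise_sd)
  dbp <- params$dbp0 + 0.5 * params$resp_pump_gain * mod +
    0.5 * params$mayer_gain * mayer +
    stats::rnorm(length(tb), sd = 0.5 * params$bp_beat_noise_sd)
  if (any(dbp >= sbp))
    stop("parameter error: DBP >= SBP in a generated beat", call. = FALSE)
  cbp <- rep(params$dbp0, n)
  nb <- length(tb)
  for (k in seq_len(nb)) {
    t_end <- if (k < nb) tb[k + 1] else min(tb[k] + 1.2, t[n])
    lo <- max(1L, floor(tb[k] / dt) + 1L)
    hi <- min(n, ceiling(t_end / dt))
    if (hi <= lo) next
    u <- (t[lo:hi] - tb[k]) / (t_end - tb[k])
    g <- ifelse(u >= 0 & u < 0.7, sin(pi * u / 0.7)^2, 0)
    cbp[lo:hi] <- dbp[k] + (sbp[k] - dbp[k]) * g
  }
  if (params$cbp_noise_sd > 0)
    cbp <- cbp + stats::rnorm(n, sd = params$cbp_noise_sd)
  list(cbp = cbp, sbp = sbp, dbp = dbp, beat_times = tb)
}

#' Simulate one synthetic multimodal record with ground truth
#'
#' Composes [gen_respiration()], [gen_heartbeats_ipfm()] and
#' [gen_pressure()] into a [crv_record()], adds scalar channels (SpO2,
#' MAP, CO, PPV as preset constants plus noise, sampled once per second)
#' and attaches the full ground truth.
#'
#' @param params a [crv_params()].
#' @param subject_id,group_label metadata.
#' @return a [crv_record()] with a `truth` list: `beat_times`, `rri_ms`,
#'   `sbp`, `dbp`, `breath_onsets`, `rr_inst`, `params`.
#' @export
#' @examples
#' rec <- simulate_record(crv_params(duration = 150, seed = 42))
#' rec
simulate_record <- function(params = crv_params(), subject_id = "S1",
                            group_label = NA_character_) {
  stopifnot(inherits(params, "crv_params"))
  set.seed(as.integer(params$seed))
  resp <- gen_respiration(params)
  beats <- gen_heartbeats_ipfm(resp, params)
  press <- gen_pressure(beats, resp, params)
  nsec <- floor(params$duration)
  scalars <- list(
    SpO2 = pmin(100, params$spo2 + stats::rnorm(nsec, sd = 0.3)),
    MAP = params$map0 + stats::rnorm(nsec, sd = 1),
    CO = params$co + stats::rnorm(nsec, sd = 0.2),
    PPV = pmax(0, params$ppv + stats::rnorm(nsec, sd = 0.3)))
  crv_record(ecg = beats$ecg, rsp = resp$wave, cbp = press$cbp,
             fs = params$fs_out, scalars = scalars,
             subject_id = subject_id, group_label = group_label,
             truth = list(beat_times = beats$beat_times,
                          rri_ms = beats$rri_ms,
                          sbp = press$sbp, dbp = press$dbp,
                          breath_onsets = resp$onsets,
                          rr_inst = beats$rr_inst,
                          params = params))
}

#' Five-group altitude presets
#'
#' Parameter presets emulating the orderings expected across the five
#' altitude groups: heart rate and low-frequency drive rise, respiratory
#' sinus arrhythmia falls, breath-timing and coupling jitter grow with
#' altitude, and the highest group adds regime switching between high- and
#' low-coupling epochs. Scalar channels use published-style group means;
#' the presets are illustrative orderings, not fits to any human cohort.
#'
#' @return named list (`HA0`..`HA4`) of parameter override lists.
#' @export
crv_presets <- function() {
  list(
    HA0 = list(hrv_noise_gain = 20, hr0 = 65, rsa_gain = 50, lf_gain = 25, coupling_jitter = 0,
               resp_jitter = 0.05, f_resp = 0.25, spo2 = 96.8, ppv = 4.96,
               dbp0 = 70, mayer_gain = 2),
    HA1 = list(hrv_noise_gain = 18, hr0 = 68, rsa_gain = 45, lf_gain = 28, coupling_jitter = 0.3,
               resp_jitter = 0.07, f_resp = 0.26, spo2 = 94.0, ppv = 5.5,
               dbp0 = 71, mayer_gain = 2.5),
    HA2 = list(hrv_noise_gain = 14, hr0 = 72, rsa_gain = 40, lf_gain = 32, coupling_jitter = 0.5,
               resp_jitter = 0.09, f_resp = 0.27, spo2 = 88.2, ppv = 6.77,
               dbp0 = 72, mayer_gain = 3),
    HA3 = list(hrv_noise_gain = 8, hr0 = 75, rsa_gain = 36, lf_gain = 36, coupling_jitter = 0.7,
               resp_jitter = 0.12, f_resp = 0.28, spo2 = 86.1, ppv = 7.34,
               dbp0 = 73, mayer_gain = 3.5),
    HA4 = list(hrv_noise_gain = 3, hr0 = 78, rsa_gain = 30, lf_gain = 40, coupling_jitter = 1.0,
               resp_jitter = 0.20, f_resp = 0.29, spo2 = 82.1, ppv = 7.44,
               dbp0 = 76.5, mayer_gain = 4,
               regime_switch = list(period = 20, depth = 1.2)))
}

#' Simulate a five-group cohort
#'
#' @param n_per_group records per group (>= 2).
#' @param seed integer master seed; per-record seeds are derived from it,
#'   so identical seeds give identical cohorts.
#' @param presets preset list, see [crv_presets()]; subset to fewer groups
#'   if desired.
#' @param duration record length, s.
#' @param ... further overrides applied to every record's [crv_params()].
#' @return list with `records` (list of [crv_record()]) and `presets`
#'   (the preset table used, as a data.frame).
#' @export
simulate_cohort <- function(n_per_group = 12, seed = 1L,
                            presets = crv_presets(), duration = 300, ...) {
  stopifnot(n_per_group >= 2)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max %/% 2,
                          n_per_group * length(presets))
  extra <- list(...)
  records <- list()
  i <- 0L
  for (g in names(presets)) {
    for (k in seq_len(n_per_group)) {
      i <- i + 1L
      args <- c(presets[[g]], extra,
                list(duration = duration, seed = sub_seeds[i]))
      args <- args[!duplicated(names(args))]
      p <- do.call(crv_params, args)
      records[[i]] <- simulate_record(p, subject_id = sprintf("%s_%02d", g, k),
                                      group_label = g)
    }
  }
  ptab <- do.call(rbind, lapply(names(presets), function(g) {
    pp <- presets[[g]]
    data.frame(group = g, hr0 = pp$hr0, rsa_gain = pp$rsa_gain,
               lf_gain = pp$lf_gain, coupling_jitter = pp$coupling_jitter,
               resp_jitter = pp$resp_jitter, f_resp = pp$f_resp,
               regime_switch = !is.null(pp$regime_switch))
  }))
  list(records = records, presets = ptab)
}

#' Write a simulated record as per-channel CSV files plus truth JSON
#'
#' @param record a [crv_record()] from [simulate_record()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_record_csv <- function(record, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  t <- (seq_along(record$ecg) - 1) / record$fs
  for (ch in c("ecg", "rsp", "cbp"))
    utils::write.csv(data.frame(time_s = t, value = record[[ch]]),
                     file.path(dir, paste0(record$subject_id, "_", ch, ".csv")),
                     row.names = FALSE)
  for (ch in names(record$scalars))
    utils::write.csv(data.frame(time_s = seq_along(record$scalars[[ch]]) - 1,
                                value = record$scalars[[ch]]),
                     file.path(dir, paste0(record$subject_id, "_", ch, ".csv")),
                     row.names = FALSE)
  if (!is.null(record$truth)) {
    tr <- record$truth
    tr$params <- unclass(tr$params)
    tr$params$regime_switch <- tr$params$regime_switch %||% "off"
    jsonlite::write_json(tr, file.path(dir, paste0(record$subject_id,
                                                   "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
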