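test_that("metronomic breathing passes through the pipeline unchanged", {
  rec <- quiet_record(seed = 17, duration = 200, resp_jitter = 0,
                      f_resp = 0.25)
  u <- condition_rsp(rec$rsp, rec$fs)
  rf <- resp_features(segment_breaths(u))
  expect_equal(unname(rf[["BR"]]), 0.25, tolerance = 0.04)
  expect_lt(rf[["BR_CV"]], 0.02)
})

test_that("breath-timing jitter raises breathing-rate variability", {
  brcv <- function(jit, seed) {
    p <- crv_params(duration = 200, seed = seed, resp_jitter = jit,
                    rsp_noise_sd = 0)
    rec <- simulate_record(p)
    u <- condition_rsp(rec$rsp, rec$fs)
    resp_features(segment_breaths(u))[["BR_CV"]]
  }
  lo <- vapply(1:10, function(s) brcv(0.05, 200 + s), 0)
  hi <- vapply(1:10, function(s) brcv(0.2, 200 + s), 0)
  expect_gt(mean(hi), mean(lo))
})

test_that("unmodulated 60 bpm heart gives exactly 1000 ms intervals", {
  rec <- quiet_record(seed = 18, duration = 150, hr0 = 60, rsa_gain = 0,
                      lf_gain = 0, hrv_noise_gain = 0, resp_jitter = 0)
  expect_true(all(abs(rec$truth$rri_ms - 1000) < 1e-6))
  det <- detect_r_peaks(condition_ecg(rec$ecg, rec$fs), rec$fs)
  expect_true(all(abs(det$values - 1000) <= 1000 / rec$fs + 1e-6))
})

test_that("beat detection recovers IPFM ground truth within 10 ms", {
  rec <- quiet_record(seed = 19, duration = 150)
  pk <- attr(detect_r_peaks(condition_ecg(rec$ecg, rec$fs), rec$fs),
             "peak_times")
  err <- vapply(rec$truth$beat_times, function(x) min(abs(pk - x)), 0)
  expect_lt(max(err), 0.010)
})

test_that("unmodulated pressure recovers baseline values", {
  rec <- quiet_record(seed = 20, duration = 150, resp_pump_gain = 0,
                      mayer_gain = 0)
  expect_true(all(rec$truth$sbp == 115))
  expect_true(all(rec$truth$dbp == 70))
  out <- condition_cbp_and_detect_beats(rec$cbp, rec$fs)
  expect_equal(mean(out$sbp$values), 115, tolerance = 0.01)
  expect_equal(length(out$sbp$times), length(rec$truth$sbp), tolerance = 0.02)
})

test_that("impossible pressure parameters are rejected", {
  p <- crv_params(duration = 150, seed = 21, sbp0 = 80, dbp0 = 79.5,
                  resp_pump_gain = 2)
  expect_error(simulate_record(p), "DBP >= SBP")
  expect_error(crv_params(hr0 = 30), "hr0")
  expect_error(crv_params(f_resp = 0.6), "f_resp")
})

test_that("waveforms are finite and within physiological ranges", {
  rec <- simulate_record(crv_params(duration = 150, seed = 22,
                                    coupling_jitter = 0.5))
  expect_true(all(is.finite(rec$ecg)))
  expect_true(all(is.finite(rec$rsp)))
  expect_true(all(is.finite(rec$cbp)))
  expect_true(all(rec$cbp > 40 & rec$cbp < 180))
  expect_true(all(rec$truth$rri_ms > 300 & rec$truth$rri_ms < 2000))
  expect_true(all(rec$scalars$SpO2 <= 100))
})

test_that("identical seeds reproduce identical cohorts", {
  c1 <- simulate_cohort(n_per_group = 2, seed = 5, duration = 150)
  c2 <- simulate_cohort(n_per_group = 2, seed = 5, duration = 150)
  expect_identical(c1$records[[1]]$ecg, c2$records[[1]]$ecg)
  expect_identical(c1$records[[10]]$cbp, c2$records[[10]]$cbp)
  expect_equal(nrow(c1$presets), 5)
  expect_false(identical(c1$records[[1]]$ecg,
                         simulate_cohort(n_per_group = 2, seed = 6,
                                         duration = 150)$records[[1]]$ecg))
})

test_that("removing the RSA drive collapses cardiorespiratory locking", {
  locked <- vapply(1:4, function(s)
    rsp_rri_sync(crv_params(duration = 300, seed = 300 + s,
                            coupling_jitter = 0))$rho, 0)
  uncoupled <- vapply(1:4, function(s)
    rsp_rri_sync(crv_params(duration = 300, seed = 300 + s,
                            rsa_gain = 0))$rho, 0)
  expect_gt(mean(locked), 0.9)
  expect_gt(mean(locked) - mean(uncoupled), 0.3)
})

test_that("respiratory pumping drives pressure synchrony above a shuffled control", {
  sync_sbp <- function(seed, shuffle) {
    p <- crv_params(duration = 300, seed = seed, coupling_jitter = 0)
    rec <- simulate_record(p)
    prep <- preprocess_record(rec, apply_notch = FALSE)
    s_rsp <- eemd(prep$rsp, seed = seed + 1)
    s_sbp <- eemd(prep$sbp, seed = seed + 2)
    dom <- select_dominant_imf(s_rsp)
    j <- match_imf_by_frequency(s_sbp, mean_inst_freq(s_rsp, dom))
    phi1 <- s_rsp$phase[, dom]
    if (shuffle) {
      # circularly shift respiration phase by ~1/3 record: destroys alignment
      n <- length(phi1)
      k <- floor(n / 3)
      phi1 <- c(phi1[(k + 1):n], phi1[1:k] + (phi1[n] - phi1[1]))
    }
    mean(phase_sync_series(phi1, s_sbp$phase[, j])$rho)
  }
  coup <- vapply(1:4, function(s) sync_sbp(500 + s, FALSE), 0)
  ctrl <- vapply(1:4, function(s) sync_sbp(500 + s, TRUE), 0)
  expect_gt(mean(coup) - mean(ctrl), 0.2)
})

test_that("records round-trip through CSV with ground truth attached", {
  rec <- simulate_record(crv_params(duration = 150, seed = 23),
                         subject_id = "T1", group_label = "HA0")
  dir <- tempfile("recs")
  write_record_csv(rec, dir)
  back <- read_record_csv(file.path(dir, "T1_ecg.csv"),
                          file.path(dir, "T1_rsp.csv"),
                          file.path(dir, "T1_cbp.csv"),
                          scalar_files = c(SpO2 = file.path(dir, "T1_SpO2.csv")),
                          subject_id = "T1", group_label = "HA0")
  expect_equal(back$fs, rec$fs)
  expect_equal(back$ecg, rec$ecg, tolerance = 1e-6)
  expect_equal(back$scalars$SpO2, rec$scalars$SpO2, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "T1_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$beat_times, rec$truth$beat_times, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
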