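test_that("time-domain HRV metrics match hand calculations", {
  expect_equal(unname(hrv_time(c(1000, 1000, 1000))), c(1000, 0))
  ht <- hrv_time(c(900, 1100))
  expect_equal(unname(ht[1]), 1000)
  expect_equal(unname(ht[2]), sd(c(900, 1100)))
  expect_error(hrv_time(1000), "2 intervals")
})

test_that("sinusoidal RSA yields SDNN near amplitude over sqrt(2)", {
  rec <- quiet_record(seed = 10, rsa_gain = 50, lf_gain = 0,
                      hrv_noise_gain = 0, resp_jitter = 0)
  expect_equal(sd(rec$truth$rri_ms), 50 / sqrt(2), tolerance = 0.1)
})

test_that("spectral band powers land in the right HRV bands", {
  tk <- seq(0, 300, by = 0.9)
  hf_only <- hrv_freq(beat_series(tk, 1000 + 50 * sin(2 * pi * 0.25 * tk),
                                  kind = "RRI"))
  expect_gte(hf_only[["HF"]] / (hf_only[["LF"]] + hf_only[["HF"]]), 0.95)
  lf_only <- hrv_freq(beat_series(tk, 1000 + 50 * sin(2 * pi * 0.10 * tk),
                                  kind = "RRI"))
  expect_gte(lf_only[["LF"]] / (lf_only[["LF"]] + lf_only[["HF"]]), 0.95)
  expect_equal(lf_only[["LF_HF"]], lf_only[["LF"]] / lf_only[["HF"]])
  expect_equal(lf_only[["logLF"]], log(lf_only[["LF"]]))
  expect_error(hrv_freq(beat_series(1:100, rnorm(100, 1000), kind = "RRI")),
               "120 s")
})

test_that("white R-R modulation gives LF/HF near the bandwidth ratio", {
  tk <- seq(0, 300, by = 0.9)
  set.seed(11)
  r <- replicate(20, {
    b <- beat_series(tk, 1000 + 30 * rnorm(length(tk)), kind = "RRI")
    hrv_freq(b)[["LF_HF"]]
  })
  expect_equal(mean(r), 0.11 / 0.25, tolerance = 0.30)
})

test_that("Welch spectrum conserves variance (Parseval)", {
  set.seed(12)
  ratio <- replicate(5, {
    tk <- seq(0, 300, by = 0.9)
    b <- beat_series(tk, 1000 + 30 * rnorm(length(tk)) +
                       40 * sin(2 * pi * 0.25 * tk), kind = "RRI")
    u <- resample_uniform(b$times, b$values, 4)
    y <- u$values - mean(u$values)
    tt <- seq_along(y)
    y <- stats::residuals(stats::lm(y ~ tt))
    ps <- crvcoupling:::welch_psd(y, 4, seg_len = 600)
    sum(ps$psd) * (ps$freq[2] - ps$freq[1]) / var(y)
  })
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("sample entropy: constants, oracle match, smoothing effect", {
  expect_equal(sampen(rep(7, 200)), 0)
  set.seed(13)
  x <- rnorm(400)
  expect_equal(sampen(x), brute_sampen(x, 2, 0.2 * sd(x)), tolerance = 1e-12)
  # equals rcmse scale 1 with matched tolerance
  expect_equal(sampen(x, r_fraction = 0.15),
               unname(rcmse(x, r_fraction = 0.15)["scale1"]),
               tolerance = 1e-12)
  # smoothing lowers entropy (seed-averaged)
  set.seed(14)
  d <- replicate(10, {
    w <- rnorm(500)
    sm <- stats::filter(w, rep(1 / 5, 5), sides = 2)
    sm <- sm[!is.na(sm)]
    sampen(w) - sampen(sm)
  })
  expect_gt(mean(d), 0)
})

test_that("breath segmentation of a symmetric sinusoid", {
  eff <- uniform_series(0.99 * sin(2 * pi * 0.25 * seq(0, 120, by = 1 / 8)),
                        fs = 8)
  br <- segment_breaths(eff)
  expect_equal(mean(br$duration), 4.0, tolerance = 0.01)
  expect_equal(mean(br$inhale), 2.0, tolerance = 0.05)
  expect_equal(mean(br$exhale), 2.0, tolerance = 0.05)
  # duty cycles partition each breath
  expect_true(all(abs(br$inhale + br$exhale - br$duration) < 1e-9))
  expect_true(all(br$inhale / br$duration > 0 & br$inhale / br$duration < 1))
  expect_error(segment_breaths(uniform_series(rep(-0.5, 800) +
                                                0.01 * sin(1:800), fs = 8)),
               "breath")
})

test_that("breath onsets match generator truth", {
  rec <- quiet_record(seed = 15, duration = 200, resp_jitter = 0.05)
  u <- condition_rsp(rec$rsp, rec$fs)
  br <- segment_breaths(u)
  err <- vapply(br$onset, function(o)
    min(abs(rec$truth$breath_onsets - o)), 0)
  expect_lt(stats::median(err), 0.25)
})

test_that("respiratory features from hand-enumerable breath tables", {
  per <- data.frame(onset = seq(0, 36, by = 4))
  per$in_end <- per$onset + 1.6
  per$next_onset <- per$onset + 4
  per$inhale <- 1.6; per$exhale <- 2.4; per$duration <- 4
  rf <- resp_features(per)
  expect_equal(unname(rf[c("BR", "BR_CV", "EDC_CV", "IDC_CV")]),
               c(0.25, 0, 0, 0))
  expect_equal(unname(rf[c("AED", "AID")]), c(2.4, 1.6))
  # alternating 3 s / 5 s breaths
  dur <- rep(c(3, 5), 4)
  alt <- data.frame(onset = cumsum(c(0, dur[-8])))
  alt$next_onset <- alt$onset + dur
  alt$in_end <- alt$onset + dur / 2
  alt$inhale <- dur / 2; alt$exhale <- dur / 2; alt$duration <- dur
  rf2 <- resp_features(alt)
  expect_equal(unname(rf2[["BR"]]), 1 / 4)
  rates <- 1 / dur
  expect_equal(unname(rf2[["BR_CV"]]), sd(rates) / mean(rates))
  expect_error(resp_features(per[1:2, ]), "3 breaths")
})

test_that("hemodynamic summaries compute mean and standard error", {
  h <- hemo_summary(list(SBP = c(80, 80, 80), DBP = c(70, 90)))
  expect_equal(h$mean, c(80, 80))
  expect_equal(h$se, c(0, 10))
  h2 <- hemo_summary(list(SpO2 = numeric(0)))
  expect_true(h2$missing)
  expect_true(is.na(h2$mean))
  rec <- quiet_record(seed = 16, duration = 150, spo2 = 82.1)
  h3 <- hemo_summary(rec$scalars)
  expect_equal(h3$mean[h3$channel == "SpO2"], 82.1, tolerance = 0.005)
})

test_that("breathing-rate check against the fixed HF band", {
  expect_true(br_in_hf_band(0.25))
  expect_false(br_in_hf_band(0.12))
  expect_false(br_in_hf_band(0.45))
})
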