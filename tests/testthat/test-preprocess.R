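test_that("notch filter removes 50 Hz while preserving the passband", {
  fs <- 250
  s50 <- tone(50, fs, 20)
  s1 <- tone(1, fs, 20)
  out50 <- notch_50hz(s50, fs)
  expect_lt(sqrt(mean(out50^2)), 0.05 * sqrt(mean(s50^2)))
  out1 <- notch_50hz(s1, fs)
  expect_lt(abs(sqrt(mean(out1^2)) / sqrt(mean(s1^2)) - 1), 0.02)
  mix <- s1 + s50
  outm <- notch_50hz(mix, fs)
  expect_lt(tone_power(outm, fs, 50), 0.01 * tone_power(mix, fs, 50))
  expect_error(notch_50hz(s1, 90), "100 Hz")
})

test_that("ECG conditioning removes DC and attenuates 60 Hz", {
  fs <- 250
  x <- tone(10, fs, 20) + 10
  y <- condition_ecg(x, fs)
  expect_lt(abs(mean(y)), 0.1)  # input offset 10 mV
  g10 <- sqrt(mean(condition_ecg(tone(10, fs, 20), fs)^2))
  g60 <- sqrt(mean(condition_ecg(tone(60, fs, 20), fs)^2))
  expect_gt(20 * log10(g10 / g60), 20)
})

test_that("ECG conditioning preserves R-peak amplitudes within 10%", {
  rec <- quiet_record(seed = 4, duration = 150)
  f <- condition_ecg(rec$ecg, rec$fs)
  idx <- round(rec$truth$beat_times * rec$fs) + 1
  idx <- idx[idx > rec$fs & idx < length(f) - rec$fs]
  pk_pre <- vapply(idx, function(i) max(rec$ecg[(i - 10):(i + 10)]), 0)
  pk_post <- vapply(idx, function(i) max(f[(i - 10):(i + 10)]), 0)
  expect_lt(median(abs(pk_post - pk_pre) / pk_pre), 0.10)
})

test_that("R-peak detection recovers regular and generator beat times", {
  fs <- 250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  ecg <- rowSums(vapply(seq(0.5, 59.5, by = 1),
                        function(tb) exp(-((t - tb)^2) / (2 * 0.012^2)),
                        numeric(length(t))))
  b <- detect_r_peaks(ecg, fs)
  # within one sample period of 1000 ms
  expect_true(all(abs(b$values - 1000) <= 1000 / fs + 1e-6))
  rec <- quiet_record(seed = 5, duration = 150)
  det <- detect_r_peaks(condition_ecg(rec$ecg, rec$fs), rec$fs)
  pk <- attr(det, "peak_times")
  err <- vapply(rec$truth$beat_times, function(x) min(abs(pk - x)), 0)
  expect_lt(max(err), 0.010)
  expect_error(detect_r_peaks(rep(0, 5000), fs), "flatline|no peaks")
})

test_that("R-R cleaning applies the four exclusion rules in order", {
  mk <- function(v) beat_series(cumsum(v) / 1000, v, kind = "RRI")
  out1 <- suppressWarnings(clean_rri(mk(c(900, 910, 2100, 905))))
  expect_equal(out1$values, c(900, 910, 905))
  expect_equal(attr(out1, "n_removed"), 1L)
  out2 <- suppressWarnings(clean_rri(mk(c(800, 810, 1050, 805))))
  expect_equal(out2$values, c(800, 810, 805))
  out3 <- suppressWarnings(
    clean_rri(mk(c(1000, 1000, 1000, 1000, 1000, 790))))
  expect_equal(out3$values, rep(1000, 5))
  # below-300 rule
  out4 <- suppressWarnings(clean_rri(mk(c(900, 910, 250, 905))))
  expect_equal(out4$values, c(900, 910, 905))
})

test_that("R-R cleaning is idempotent and flags heavy removal", {
  set.seed(9)
  v <- 1000 + c(rnorm(40, sd = 30), 2500, 250, rnorm(10, sd = 30))
  b <- beat_series(cumsum(abs(v)) / 1000, v, kind = "RRI")
  c1 <- suppressWarnings(clean_rri(b))
  c2 <- clean_rri(c1)
  expect_identical(c1$values, c2$values)
  expect_equal(attr(c2, "n_removed"), 0L)
  bad <- beat_series(cumsum(rep(1, 10)), rep(c(1000, 2500), 5), kind = "RRI")
  expect_warning(clean_rri(bad), "quality")
})

test_that("uniform resampling reproduces constants, sines, and grids", {
  tt <- cumsum(rep(1, 40))
  u <- resample_uniform(tt, rep(1000, 40), 8)
  expect_true(all(abs(u$values - 1000) < 1e-9))
  # sine sampled at beat-like times
  set.seed(21)
  tb <- cumsum(runif(300, 0.8, 1.0))
  y <- sin(2 * pi * 0.1 * tb)
  u2 <- resample_uniform(tb, y, 8)
  grid2 <- u2$t0 + (seq_along(u2$values) - 1) / 8
  ref <- sin(2 * pi * 0.1 * grid2)
  expect_lt(max(abs(u2$values - ref)[20:(length(ref) - 20)]), 1e-3)
  expect_error(resample_uniform(1:3, 1:3, 8), "4 support")
  # identity on an already-uniform grid at the same rate
  g <- seq(0, 50, by = 1 / 8)
  v <- sin(g)
  u3 <- resample_uniform(g, v, 8)
  expect_lt(max(abs(u3$values - v)), 1e-9)
})

test_that("respiration conditioning is a band-passed derivative in (-1,1)", {
  fs <- 250
  x <- -cos(2 * pi * 0.25 * seq(0, 120 - 1 / fs, by = 1 / fs))
  u <- condition_rsp(x, fs)
  expect_true(all(u$values > -1 & u$values < 1))
  # derivative of -cos is +sin: maxima where input rises fastest
  tt <- u$t0 + (seq_along(u$values) - 1) / u$fs
  ref <- sin(2 * pi * 0.25 * tt)
  core <- 50:(length(tt) - 50)
  expect_gt(cor(u$values[core], ref[core]), 0.99)
  expect_error(condition_rsp(rep(3, 1000), fs), "degenerate")
  # high-frequency noise removed by the 2 Hz cutoff
  xn <- x + 0.3 * sin(2 * pi * 5 * seq(0, 120 - 1 / fs, by = 1 / fs))
  un <- condition_rsp(xn, fs)
  pk <- tone_power(un$values, 8, 0.25)
  p5 <- tone_power(un$values, 8, 3.75) # 5 Hz aliases to 3 Hz at 8 Hz; check near Nyquist
  expect_gt(pk, 10 * p5)
})

test_that("effort zero crossings sit at extrema of the band-passed input", {
  fs <- 8
  x <- -cos(2 * pi * 0.25 * seq(0, 120 - 1 / fs, by = 1 / fs))
  u <- condition_rsp(x, fs)
  zc <- which(diff(sign(u$values)) != 0) / fs + u$t0
  # input extrema at multiples of 2 s
  near <- vapply(zc, function(z) min(abs(z - seq(0, 120, by = 2))), 0)
  expect_lt(stats::median(near), 0.3)
})

test_that("pressure landmark detection recovers per-beat truth", {
  rec <- quiet_record(seed = 6, duration = 150)
  out <- condition_cbp_and_detect_beats(rec$cbp, rec$fs)
  expect_equal(length(out$sbp$times), length(rec$truth$sbp), tolerance = 0.02)
  # match detected peaks to truth beats
  tb <- rec$truth$beat_times
  for (k in sample(seq_along(out$sbp$times), 25)) {
    j <- which.min(abs(tb - out$sbp$times[k]))
    expect_lt(abs(out$sbp$values[k] - rec$truth$sbp[j]), 2)
  }
  db_err <- abs(mean(out$dbp$values) - mean(rec$truth$dbp))
  expect_lt(db_err, 2)
  expect_error(condition_cbp_and_detect_beats(rep(80, 5000), 250), "empty|constant")
  # 1 Hz pulse train: one beat per second
  fs <- 250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  pulse <- 80 + 40 * pmax(sin(2 * pi * 1 * t), 0)^2
  out2 <- condition_cbp_and_detect_beats(pulse, fs)
  expect_lte(abs(length(out2$sbp$times) - 60), 1)
})

test_that("preprocessed RRI tracks ground truth on a clean record", {
  rec <- quiet_record(seed = 7)
  prep <- preprocess_record(rec, apply_notch = FALSE)
  g <- prep$rri$t0 + (seq_along(prep$rri$values) - 1) / prep$rri$fs
  tb <- rec$truth$beat_times
  truth <- stats::approx(tb[-1], diff(tb) * 1000, xout = g, rule = 2)$y
  expect_gt(cor(prep$rri$values, truth), 0.99)
})
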