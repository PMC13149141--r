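# Small signal fixtures built in code.

tone <- function(f, fs, dur, amp = 1, phase = 0) {
  amp * sin(2 * pi * f * seq(0, dur - 1 / fs, by = 1 / fs) + phase)
}

# A short clean synthetic record (noise-free channels unless stated).
quiet_record <- function(seed = 1, duration = 300, ...) {
  p <- crv_params(duration = duration, seed = seed,
                  ecg_noise_sd = 0, rsp_noise_sd = 0, cbp_noise_sd = 0,
                  bp_beat_noise_sd = 0, ...)
  simulate_record(p)
}

# Mean RSP-RRI synchronization for one simulated record (single-pair run,
# skipping the three pressure decompositions for speed).
rsp_rri_sync <- function(params) {
  rec <- simulate_record(params)
  prep <- preprocess_record(rec, apply_notch = FALSE)
  s_rsp <- eemd(prep$rsp, seed = params$seed + 1)
  s_rri <- eemd(prep$rri, seed = params$seed + 2)
  dom <- select_dominant_imf(s_rsp)
  j <- match_imf_by_frequency(s_rri, mean_inst_freq(s_rsp, dom))
  ss <- phase_sync_series(s_rsp$phase[, dom], s_rri$phase[, j])
  list(rho = mean(ss$rho), sync = ss, prep = prep)
}
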