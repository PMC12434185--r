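# ECG bandpass response, SQI behaviour, QC segment rules, gain calibration.

test_that("ECG bandpass attenuates sub-band drift and passes in-band content", {
  # designed-filter frequency response of the zero-phase cascade
  expect_lt(ecg_filter_gain(2000, 0.01), 10^(-20 / 20))
  expect_lt(abs(ecg_filter_gain(2000, 10) - 1), 0.01)
  expect_identical(bandpass_ecg(numeric(5000), 2000), numeric(5000))
  expect_error(ecg_filter_design(250), "fs_hz")
})

test_that("preprocessing chain is zero-phase: clean event timing shifts < 2 ms", {
  sim <- generate_recording(hemodynamic_profile(rr_jitter_ms = 0),
                            noise_spec(seed = 3), duration_ms = 8000)
  rec <- sim$recording
  fs <- rec$fs_hz
  # R-peak location before and after the ECG bandpass
  k <- 3
  w <- acgtools:::ms_to_idx(sim$truth$qrs_onset_ms[k], fs) + 0:200
  before <- w[which.max(rec$ecg[w])]
  after <- w[which.max(bandpass_ecg(rec$ecg, fs)[w])]
  expect_lt(abs(before - after) * 1000 / fs, 2)
  # S2 envelope peak before and after PCG denoising
  w2 <- acgtools:::ms_to_idx(sim$truth$s2_peak_ms[k] - 80, fs) + 0:320
  env_b <- pcg_envelope(rec$pcg, fs)
  env_a <- pcg_envelope(denoise_pcg(rec$pcg, fs), fs)
  expect_lt(abs(w2[which.max(env_b[w2])] - w2[which.max(env_a[w2])]) *
              1000 / fs, 2)
})

test_that("SQI is high on clean recordings, low on noise, zero below 3 beats", {
  sim <- generate_recording(hemodynamic_profile(),
                            noise_spec(pcg_snr_db = 20, seed = 2),
                            duration_ms = 12000)
  expect_gte(compute_sqi(sim$recording$pcg, 2000, sim$truth$qrs_onset_ms),
             0.8)
  set.seed(31)
  wn <- rnorm(24000)
  expect_lt(compute_sqi(wn, 2000, seq(400, 11000, by = 800)), 0.5)
  expect_warning(s <- compute_sqi(wn, 2000, c(400, 1200)), "3 beats")
  expect_equal(s, 0)
})

test_that("SQI is monotonically non-increasing in added noise power", {
  levels <- c(30, 20, 10, 5, 0)
  for (seed in c(42, 43, 44)) {
    sqis <- vapply(levels, function(snr) {
      sim <- generate_recording(hemodynamic_profile(),
                                noise_spec(pcg_snr_db = snr, seed = seed),
                                duration_ms = 10000)
      compute_sqi(sim$recording$pcg, 2000, sim$truth$qrs_onset_ms)
    }, numeric(1))
    expect_true(all(diff(sqis) <= 1e-6),
                info = paste("seed", seed, ":",
                             paste(round(sqis, 5), collapse = " ")))
  }
})

test_that("QC flags motion above 0.5 g and recording-level drift above 1 mV", {
  base <- noise_spec(pcg_snr_db = 20, ecg_snr_db = 30, seed = 2)
  clean <- generate_recording(hemodynamic_profile(), base,
                              duration_ms = 12000)
  qc <- qc_segments(clean$recording)
  expect_true(qc$valid)
  expect_equal(nrow(qc$segment_flags), 0)
  # idempotence: same recording, identical report
  expect_identical(qc_segments(clean$recording), qc)

  burst <- generate_recording(
    hemodynamic_profile(),
    noise_spec(pcg_snr_db = 20, ecg_snr_db = 30, seed = 2,
               motion_bursts = list(c(2000, 2500, 0.8))),
    duration_ms = 12000)
  qc2 <- qc_segments(burst$recording)
  mo <- qc2$segment_flags[qc2$segment_flags$reason == "motion", ]
  expect_equal(nrow(mo), 1)
  expect_gte(mo$start_ms, 2000)
  expect_lte(mo$end_ms, 2500)
  expect_false(qc2$valid)

  drift <- generate_recording(
    hemodynamic_profile(),
    noise_spec(pcg_snr_db = 20, ecg_snr_db = 30, seed = 2,
               baseline_drift_mv = 1.5, drift_freq_hz = 0.2),
    duration_ms = 12000)
  qc3 <- qc_segments(drift$recording)
  expect_true("drift" %in% qc3$segment_flags$reason)
  expect_false(qc3$valid)
})

test_that("gain calibration restores attenuated recordings within the 30% limit", {
  sim <- generate_recording(hemodynamic_profile(),
                            noise_spec(pcg_snr_db = 20, ecg_snr_db = 30,
                                       seed = 2),
                            duration_ms = 12000)
  refs <- sim$truth$qrs_onset_ms
  target <- max(pcg_envelope(sim$recording$pcg, 2000))

  g <- gain_calibrate(sim$recording$pcg * 0.8, 2000, refs,
                      target_amp = target)
  expect_equal(g$gain_applied, 1.25, tolerance = 0.02)
  expect_lt(g$s1_amplitude_cv, 0.08)
  expect_false(g$limited)

  g2 <- gain_calibrate(sim$recording$pcg, 2000, refs)
  expect_identical(g2$gain_applied, 1)

  expect_warning(
    g3 <- gain_calibrate(sim$recording$pcg * 0.5, 2000, refs,
                         target_amp = target),
    "calibration limit")
  expect_equal(g3$gain_applied, 1.3)
  expect_true(g3$limited)

  expect_error(gain_calibrate(sim$recording$pcg, 2000, refs[1:3]), ">= 5")
})
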