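# QRS and heart-sound detection: detection counts, timing accuracy,
# gating, robustness to noise, beat-level rejection.

test_that("clean ECG at 60 bpm yields one detection per beat within 10 ms", {
  sim <- generate_recording(hemodynamic_profile(heart_rate_bpm = 60,
                                                rr_jitter_ms = 0),
                            noise_spec(seed = 1), duration_ms = 10000)
  qrs <- detect_qrs(bandpass_ecg(sim$recording$ecg, 2000), 2000)
  expect_true(abs(nrow(qrs) - nrow(sim$truth)) <= 1)
  m <- vapply(sim$truth$qrs_onset_ms,
              function(o) min(abs(qrs$qrs_onset_ms - o)), numeric(1))
  expect_true(all(m < 10))
  expect_true(all(diff(qrs$qrs_onset_ms) > 0))
})

test_that("a flat-line ECG yields no detections, with a warning", {
  expect_warning(qrs <- detect_qrs(numeric(10000), 2000), "no QRS")
  expect_equal(nrow(qrs), 0)
})

test_that("detected mean RR scales with heart rate", {
  rr <- vapply(c(100, 60), function(hr) {
    sim <- generate_recording(hemodynamic_profile(heart_rate_bpm = hr,
                                                  rr_jitter_ms = 0),
                              noise_spec(seed = 2), duration_ms = 10000)
    q <- detect_qrs(bandpass_ecg(sim$recording$ecg, 2000), 2000)
    mean(diff(q$qrs_onset_ms))
  }, numeric(1))
  expect_equal(rr[1] / rr[2], 0.6, tolerance = 0.02)
})

test_that("noiseless round-trip recovers every event within 2 sample periods", {
  out <- run_pipeline(hemodynamic_profile(rr_jitter_ms = 15),
                      noise_spec(seed = 9), duration_ms = 12000)
  b <- out$res$beats
  tr <- out$sim$truth
  expect_true(all(b$valid))
  m <- match_beats(b, tr)
  tol <- 2 * 1000 / 2000  # 2 sample periods, ms
  for (ev in c("qrs_onset_ms", "s1_onset_ms", "s1_peak_ms", "s1_end_ms",
               "s2_onset_ms", "s2_peak_ms")) {
    expect_true(all(abs(b[[ev]][m] - tr[[ev]]) <= tol),
                info = paste(ev, "max err",
                             max(abs(b[[ev]][m] - tr[[ev]]))))
  }
})

test_that("event-timing error grows as the PCG SNR falls", {
  levels <- c(30, 20, 10, 0)
  maes <- vapply(c(42, 43, 44), function(seed) {
    vapply(levels, function(snr) {
      out <- run_pipeline(hemodynamic_profile(),
                          noise_spec(pcg_snr_db = snr, ecg_snr_db = 30,
                                     seed = seed),
                          duration_ms = 10000)
      b <- out$res$beats
      m <- match_beats(b, out$sim$truth)
      mean(abs(b$s2_peak_ms[m] - out$sim$truth$s2_peak_ms), na.rm = TRUE)
    }, numeric(1))
  }, numeric(length(levels)))
  med <- apply(maes, 1, stats::median)
  # non-decreasing as SNR decreases, with a small numerical allowance
  expect_true(all(diff(med) >= -0.15),
              info = paste(round(med, 3), collapse = " "))
  expect_gt(med[length(levels)], med[1])
})

test_that("gating: S1 never precedes its QRS onset, S2 never precedes S1 end", {
  out <- run_pipeline(hemodynamic_profile(),
                      noise_spec(pcg_snr_db = 10, ecg_snr_db = 20, seed = 13),
                      duration_ms = 12000)
  b <- out$res$beats[out$res$beats$valid, ]
  expect_true(all(b$s1_onset_ms > b$qrs_onset_ms))
  expect_true(all(b$s2_peak_ms > b$s1_end_ms))
})

test_that("a beat with its S2 silenced is rejected as s2-not-found", {
  sim <- generate_recording(hemodynamic_profile(rr_jitter_ms = 0),
                            noise_spec(seed = 3), duration_ms = 12000)
  rec <- sim$recording
  k <- 5
  w <- acgtools:::ms_to_idx(sim$truth$s2_onset_ms[k] - 30, rec$fs_hz):
    acgtools:::ms_to_idx(sim$truth$s2_peak_ms[k] + 60, rec$fs_hz)
  rec$pcg[w] <- 0
  res <- process_recording(rec)
  b <- res$beats
  m <- which.min(abs(b$qrs_onset_ms - sim$truth$qrs_onset_ms[k]))
  expect_false(b$valid[m])
  expect_equal(b$rejection_reason[m], "s2-not-found")
  expect_true(all(b$valid[-m]))
})

test_that("motion-corrupted beats are rejected in proportion to corruption", {
  # 2 of ~19 beats hit by bursts -> invalid fraction near 2/19
  prof <- hemodynamic_profile(rr_jitter_ms = 0)
  sim <- generate_recording(
    prof,
    noise_spec(pcg_snr_db = 15, ecg_snr_db = 25, seed = 10,
               motion_bursts = list(c(3050, 3350, 0.9),
                                    c(9050, 9350, 1.1))),
    duration_ms = 16000)
  res <- process_recording(sim$recording)
  b <- res$beats
  frac <- mean(!b$valid)
  expected <- 2 / nrow(b)
  expect_lte(abs(frac - expected), 2 / nrow(b))
  expect_true(any(b$rejection_reason[!b$valid] %in%
                    c("motion", "poor-template-match")))
})
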