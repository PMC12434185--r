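# Simulator: ground-truth construction, determinism, noise scaling,
# motion injection.

test_that("profile and noise validation rejects non-physiologic input", {
  expect_error(hemodynamic_profile(heart_rate_bpm = 30), "heart_rate_bpm")
  expect_error(hemodynamic_profile(lvet_ms = 500), "lvet_ms")
  expect_error(hemodynamic_profile(emat_ms = 90, lvet_ms = 450,
                                   heart_rate_bpm = 120), "cardiac cycle")
  expect_error(hemodynamic_profile(s1_amplitude = 0), "amplitudes")
  expect_error(hemodynamic_profile(emat_ms = 40, s1_duration_ms = 90),
               "S1 duration")
  expect_error(noise_spec(motion_bursts = list(c(500, 400, 1))), "end")
  expect_error(generate_recording(hemodynamic_profile(), duration_ms = 2000),
               "duration")
})

test_that("ground-truth event times satisfy the interval definitions exactly", {
  prof <- hemodynamic_profile(lvet_ms = 320, emat_ms = 95, rr_jitter_ms = 5)
  sim <- generate_recording(prof, noise_spec(seed = 4), duration_ms = 8000)
  tr <- sim$truth
  expect_equal(tr$s2_peak_ms - tr$s1_end_ms, rep(320, nrow(tr)))
  expect_equal(tr$s1_peak_ms - tr$qrs_onset_ms, rep(95, nrow(tr)))
  # strict within-beat ordering
  expect_true(all(tr$qrs_onset_ms < tr$s1_onset_ms))
  expect_true(all(tr$s1_onset_ms < tr$s1_peak_ms))
  expect_true(all(tr$s1_peak_ms < tr$s1_end_ms))
  expect_true(all(tr$s1_end_ms < tr$s2_onset_ms))
  expect_true(all(tr$s2_onset_ms < tr$s2_peak_ms))
  # beats non-overlapping
  expect_true(all(diff(tr$qrs_onset_ms) > 0))
})

test_that("mean RR is exactly the nominal cycle length without jitter", {
  prof <- hemodynamic_profile(heart_rate_bpm = 75, rr_jitter_ms = 0)
  sim <- generate_recording(prof, noise_spec(seed = 1), duration_ms = 10000)
  expect_equal(mean(diff(sim$truth$qrs_onset_ms)), 800)
})

test_that("identical profile, noise and duration give bit-identical output", {
  prof <- hemodynamic_profile(rr_jitter_ms = 12)
  nz <- noise_spec(pcg_snr_db = 12, ecg_snr_db = 20, seed = 77,
                   motion_bursts = list(c(3000, 3400, 0.9)))
  a <- generate_recording(prof, nz, duration_ms = 8000)
  b <- generate_recording(prof, nz, duration_ms = 8000)
  expect_identical(a$recording$ecg, b$recording$ecg)
  expect_identical(a$recording$pcg, b$recording$pcg)
  expect_identical(a$recording$motion, b$recording$motion)
  expect_identical(a$truth, b$truth)
})

test_that("doubling the S2 amplitude doubles the S2 burst peak in the clean render", {
  p1 <- hemodynamic_profile(s2_amplitude = 0.8, rr_jitter_ms = 0)
  p2 <- hemodynamic_profile(s2_amplitude = 1.6, rr_jitter_ms = 0)
  s1 <- generate_recording(p1, noise_spec(seed = 2), duration_ms = 6000)
  s2 <- generate_recording(p2, noise_spec(seed = 2), duration_ms = 6000)
  i <- acgtools:::ms_to_idx(s1$truth$s2_peak_ms[2], 2000)
  expect_equal(s2$recording$clean$pcg[i], 2 * s1$recording$clean$pcg[i],
               tolerance = 1e-10)
})

test_that("PCG noise injection hits the requested SNR within 1 dB", {
  prof <- hemodynamic_profile()
  sim <- generate_recording(prof, noise_spec(pcg_snr_db = 10, seed = 6),
                            duration_ms = 10000)
  measured <- acgtools:::snr_db(sim$recording$pcg, sim$recording$clean$pcg)
  expect_lt(abs(measured - 10), 1)
})

test_that("motion bursts raise the motion channel and leave clean recordings unchanged", {
  prof <- hemodynamic_profile()
  sim <- generate_recording(prof, noise_spec(seed = 8), duration_ms = 8000)
  rec <- sim$recording
  # no bursts: identity
  expect_identical(inject_motion(rec, list()), rec)
  # one burst: motion max in window reaches the stated acceleration
  rec2 <- inject_motion(rec, list(c(2000, 2500, 0.8)))
  w <- acgtools:::ms_to_idx(2000, 2000):acgtools:::ms_to_idx(2500, 2000)
  expect_gte(max(rec2$motion[w]), 0.8)
  expect_true(all(rec2$motion[-(w)] <= 0.8))
  # PCG corrupted inside the burst
  expect_gt(stats::sd(rec2$pcg[w] - rec$pcg[w]), stats::sd(rec$pcg))
  # overlapping bursts are merged with a warning
  expect_warning(inject_motion(rec, list(c(1000, 1500, 0.6),
                                         c(1400, 1800, 0.9))),
                 "merged")
})

test_that("sub-threshold motion (0.4 g) is not rejected by quality control", {
  prof <- hemodynamic_profile()
  sim <- generate_recording(prof,
                            noise_spec(pcg_snr_db = 20, ecg_snr_db = 30,
                                       seed = 2,
                                       motion_bursts = list(c(2000, 2500, 0.4))),
                            duration_ms = 12000)
  qc <- qc_segments(sim$recording)
  expect_equal(nrow(qc$segment_flags), 0)
  expect_true(qc$valid)
})
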