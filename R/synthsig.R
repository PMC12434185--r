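# Synthetic synchronized ECG-PCG generator with exact ground-truth event
# times. The rendered beat is a P-QRS-T stencil on the ECG channel and two
# amplitude-modulated tone bursts (S1, S2) on the PCG channel, placed so the
# systolic intervals are true by construction:
#   s1_peak = qrs_onset + emat
#   s1_end  = s1_peak + s1_duration/2   (10%-of-peak envelope criterion)
#   s2_peak = s1_end + lvet

# full envelope width above 10% of a Gaussian peak is 2*sqrt(2*log(10))*sigma
GAUSS10 <- 2 * sqrt(2 * log(10))

#' Hemodynamic profile for the beat simulator
#'
#' Collects the per-beat timing and amplitude parameters of the simulated
#' heart: heart rate, left ventricular ejection time (LVET, end of S1 to S2
#' peak), electromechanical activation time (EMAT, QRS onset to S1 peak),
#' heart-sound burst durations and amplitudes, QRS amplitude, and beat-to-beat
#' RR jitter.
#'
#' Defaults reflect a normotensive third-trimester profile: LVET 301 ms,
#' EMAT 90 ms, heart rate 75 bpm.
#'
#' @param heart_rate_bpm Mean heart rate, beats/min (40-180).
#' @param lvet_ms Left ventricular ejection time, ms (150-450).
#' @param emat_ms Electromechanical activation time, ms (40-160). Must exceed
#'   half the S1 duration so S1 onset falls after QRS onset.
#' @param s1_duration_ms,s2_duration_ms Width of the S1/S2 bursts, defined as
#'   the span over which the noiseless envelope exceeds 10% of its peak.
#' @param s1_amplitude,s2_amplitude Peak amplitudes of the S1/S2 bursts
#'   (arbitrary PCG units).
#' @param qrs_amplitude_mv R-wave peak amplitude, mV.
#' @param rr_jitter_ms SD of beat-to-beat RR variation, ms.
#' @return An object of class `acg_profile`.
#' @export
hemodynamic_profile <- function(heart_rate_bpm = 75, lvet_ms = 301,
                                emat_ms = 90, s1_duration_ms = 70,
                                s2_duration_ms = 60, s1_amplitude = 1,
                                s2_amplitude = 0.8, qrs_amplitude_mv = 1,
                                rr_jitter_ms = 10) {
  p <- list(heart_rate_bpm = heart_rate_bpm, lvet_ms = lvet_ms,
            emat_ms = emat_ms, s1_duration_ms = s1_duration_ms,
            s2_duration_ms = s2_duration_ms, s1_amplitude = s1_amplitude,
            s2_amplitude = s2_amplitude, qrs_amplitude_mv = qrs_amplitude_mv,
            rr_jitter_ms = rr_jitter_ms)
  validate_profile(p)
  structure(p, class = "acg_profile")
}

validate_profile <- function(p) {
  stop_if(p$heart_rate_bpm < 40 || p$heart_rate_bpm > 180,
          "heart_rate_bpm must lie in [40, 180]")
  stop_if(p$lvet_ms < 150 || p$lvet_ms > 450,
          "lvet_ms must lie in [150, 450]")
  stop_if(p$emat_ms < 40 || p$emat_ms > 160,
          "emat_ms must lie in [40, 160]")
  stop_if(p$emat_ms + p$lvet_ms >= 60000 / p$heart_rate_bpm,
          "emat_ms + lvet_ms must fit inside one cardiac cycle")
  stop_if(p$emat_ms <= p$s1_duration_ms / 2,
          "emat_ms must exceed half the S1 duration (S1 onset after QRS onset)")
  amps <- c(p$s1_amplitude, p$s2_amplitude, p$qrs_amplitude_mv)
  stop_if(any(amps <= 0), "all amplitudes must be positive")
  stop_if(p$rr_jitter_ms < 0, "rr_jitter_ms must be non-negative")
  invisible(p)
}

#' Noise specification for the simulator
#'
#' @param pcg_snr_db PCG signal-to-noise ratio against the clean render, dB.
#'   `Inf` disables PCG noise.
#' @param ecg_snr_db ECG signal-to-noise ratio, dB. `Inf` disables ECG noise.
#' @param baseline_drift_mv Amplitude of a slow sinusoidal ECG baseline
#'   wander, mV (0 disables).
#' @param drift_freq_hz Frequency of the baseline wander, Hz.
#' @param motion_bursts List of numeric triples `c(start_ms, end_ms, accel_g)`
#'   describing motion artifacts to inject.
#' @param seed Integer seed; the same spec yields a bit-identical recording.
#' @return An object of class `acg_noise`.
#' @export
noise_spec <- function(pcg_snr_db = Inf, ecg_snr_db = Inf,
                       baseline_drift_mv = 0, drift_freq_hz = 0.2,
                       motion_bursts = list(), seed = 1L) {
  stop_if(baseline_drift_mv < 0, "baseline_drift_mv must be non-negative")
  stop_if(drift_freq_hz <= 0, "drift_freq_hz must be positive")
  for (b in motion_bursts) {
    stop_if(length(b) != 3, "each motion burst is c(start_ms, end_ms, accel_g)")
    stop_if(b[3] < 0, "accel_g must be non-negative")
    stop_if(b[2] <= b[1], "burst end must exceed start")
  }
  structure(list(pcg_snr_db = pcg_snr_db, ecg_snr_db = ecg_snr_db,
                 baseline_drift_mv = baseline_drift_mv,
                 drift_freq_hz = drift_freq_hz,
                 motion_bursts = motion_bursts, seed = as.integer(seed)),
            class = "acg_noise")
}

new_recording <- function(ecg, pcg, motion, fs_hz, meta = list()) {
  n <- length(ecg)
  stop_if(length(pcg) != n, "ecg and pcg traces must have equal length")
  if (!is.null(motion)) stop_if(length(motion) != n,
                                "motion trace length must match ecg/pcg")
  stop_if(fs_hz < 500, "fs_hz must be >= 500 Hz")
  stop_if(!all(is.finite(ecg)) || !all(is.finite(pcg)),
          "traces must contain finite samples only")
  structure(list(ecg = ecg, pcg = pcg, motion = motion, fs_hz = fs_hz,
                 duration_ms = n * 1000 / fs_hz, meta = meta),
            class = "acg_recording")
}

#' @export
print.acg_recording <- function(x, ...) {
  cat(sprintf("<acg_recording> %.1f s @ %g Hz (%d samples)%s\n",
              x$duration_ms / 1000, x$fs_hz, length(x$ecg),
              if (is.null(x$motion)) "" else ", motion channel"))
  invisible(x)
}

# ECG stencil for one beat, evaluated at times t (ms relative to QRS onset).
# The QRS complex (Q dip, R peak at +24 ms, S dip) is gated to start exactly
# at t = 0, so the ground-truth onset is the time the QRS deflection begins.
ecg_beat_stencil <- function(t, a) {
  qrs <- (-0.10 * exp(-(t - 10)^2 / (2 * 4^2)) +
            exp(-(t - 24)^2 / (2 * 7^2)) -
            0.15 * exp(-(t - 44)^2 / (2 * 5^2))) * (t >= 0)
  a * (qrs +
         0.10 * exp(-(t + 60)^2 / (2 * 15^2)) +    # P wave
         0.25 * exp(-(t - 300)^2 / (2 * 40^2)))    # T wave
}

QRS_PEAK_OFFSET_MS <- 24

# Gaussian-enveloped tone burst centred at `peak_ms`.
tone_burst <- function(t, peak_ms, amp, dur_ms, freq_hz) {
  sigma <- dur_ms / GAUSS10
  amp * exp(-(t - peak_ms)^2 / (2 * sigma^2)) *
    cospi(2 * freq_hz * (t - peak_ms) / 1000)
}

#' Generate a synchronized ECG-PCG recording with ground truth
#'
#' Renders a beat train on a common clock: ECG as a P-QRS-T stencil, PCG as
#' Gaussian-enveloped tone bursts (S1 at 35 Hz, S2 at 50 Hz), then adds
#' channel noise, baseline drift and motion bursts per the noise spec. Every
#' beat satisfies `s1_peak - qrs_onset = emat_ms` and
#' `s2_peak - s1_end = lvet_ms` exactly; `s1_end` is where the noiseless S1
#' envelope last exceeds 10% of its peak.
#'
#' @param profile An [hemodynamic_profile()].
#' @param noise A [noise_spec()].
#' @param duration_ms Recording length, ms (>= 5000).
#' @param fs_hz Common sampling rate for both channels, Hz (default 2000).
#' @return A list with elements `recording` (class `acg_recording`, including
#'   a `clean` component holding the noiseless render) and `truth`
#'   (data frame of per-beat ground-truth event times, ms).
#' @examples
#' sim <- generate_recording(hemodynamic_profile(), noise_spec(seed = 7),
#'                           duration_ms = 6000)
#' head(sim$truth)
#' @export
generate_recording <- function(profile, noise = noise_spec(),
                               duration_ms = 20000, fs_hz = 2000) {
  validate_profile(profile)
  stop_if(duration_ms < 5000, "duration_ms must be >= 5000")
  stop_if(fs_hz < 500, "fs_hz must be >= 500")
  for (b in noise$motion_bursts) {
    stop_if(b[2] > duration_ms, "motion burst extends beyond recording")
  }

  n <- as.integer(round(duration_ms * fs_hz / 1000))
  t_ms <- (seq_len(n) - 1) * 1000 / fs_hz
  rr_nominal <- 60000 / profile$heart_rate_bpm

  with_seed(noise$seed, {
    # beat schedule: a beat is kept only if its full S2 burst fits
    onsets <- numeric(0)
    t0 <- 400
    tail_ms <- profile$emat_ms + profile$s1_duration_ms / 2 +
      profile$lvet_ms + profile$s2_duration_ms / 2 + 50
    repeat {
      if (t0 + tail_ms > duration_ms) break
      onsets <- c(onsets, t0)
      jit <- if (profile$rr_jitter_ms > 0) {
        stats::rnorm(1, 0, profile$rr_jitter_ms)
      } else 0
      t0 <- t0 + rr_nominal + jit
    }
    stop_if(length(onsets) < 1, "duration too short for a single beat")

    s1_peak <- onsets + profile$emat_ms
    s1_half <- profile$s1_duration_ms / 2
    s2_half <- profile$s2_duration_ms / 2
    s1_end <- s1_peak + s1_half
    s2_peak <- s1_end + profile$lvet_ms
    truth <- data.frame(
      beat = seq_along(onsets),
      qrs_onset_ms = onsets,
      qrs_peak_ms = onsets + QRS_PEAK_OFFSET_MS,
      s1_onset_ms = s1_peak - s1_half,
      s1_peak_ms = s1_peak,
      s1_end_ms = s1_end,
      s2_onset_ms = s2_peak - s2_half,
      s2_peak_ms = s2_peak
    )

    ecg <- numeric(n)
    pcg <- numeric(n)
    for (k in seq_along(onsets)) {
      # evaluate the stencil only on a window around the beat, for speed
      lo <- max(1L, ms_to_idx(onsets[k] - 150, fs_hz))
      hi <- min(n, ms_to_idx(onsets[k] + rr_nominal + 150, fs_hz))
      idx <- lo:hi
      ecg[idx] <- ecg[idx] +
        ecg_beat_stencil(t_ms[idx] - onsets[k], profile$qrs_amplitude_mv)
      pcg[idx] <- pcg[idx] +
        tone_burst(t_ms[idx], s1_peak[k], profile$s1_amplitude,
                   profile$s1_duration_ms, 35) +
        tone_burst(t_ms[idx], s2_peak[k], profile$s2_amplitude,
                   profile$s2_duration_ms, 50)
    }
    clean <- list(ecg = ecg, pcg = pcg)

    add_noise <- function(x, snr) {
      if (!is.finite(snr)) return(x)
      e <- stats::rnorm(length(x))
      e <- e * sqrt(sum(x^2) / 10^(snr / 10) / sum(e^2))
      x + e
    }
    pcg <- add_noise(pcg, noise$pcg_snr_db)
    ecg <- add_noise(ecg, noise$ecg_snr_db)
    if (noise$baseline_drift_mv > 0) {
      ecg <- ecg + noise$baseline_drift_mv *
        sinpi(2 * noise$drift_freq_hz * t_ms / 1000)
    }

    rec <- new_recording(ecg, pcg, motion = numeric(n), fs_hz = fs_hz,
                         meta = list(profile = unclass(profile),
                                     noise = unclass(noise)))
    rec$clean <- clean
    if (length(noise$motion_bursts) > 0) {
      rec <- inject_motion(rec, noise$motion_bursts,
                           seed = noise$seed + 104729L)
    }
    list(recording = rec, truth = truth)
  })
}

#' Inject motion-artifact bursts into a recording
#'
#' Raises the motion (accelerometer) channel to the stated acceleration over
#' each burst window and corrupts the PCG with a broadband transient of
#' amplitude proportional to the acceleration. Overlapping bursts are merged
#' (taking the maximum acceleration) with a warning.
#'
#' @param rec An `acg_recording`.
#' @param bursts List of numeric triples `c(start_ms, end_ms, accel_g)`.
#' @param seed Seed for the broadband transient (defaults to a fixed value so
#'   repeated injection is reproducible).
#' @return The modified recording.
#' @export
inject_motion <- function(rec, bursts, seed = 2025L) {
  if (length(bursts) == 0) return(rec)
  bm <- do.call(rbind, lapply(bursts, function(b) as.numeric(b)))
  stop_if(any(bm[, 2] > rec$duration_ms + 1e-9),
          "motion burst extends beyond recording")
  ord <- order(bm[, 1])
  bm <- bm[ord, , drop = FALSE]
  # merge overlaps, keeping the max acceleration
  merged <- bm[1, , drop = FALSE]
  if (nrow(bm) > 1) {
    for (k in 2:nrow(bm)) {
      last <- nrow(merged)
      if (bm[k, 1] <= merged[last, 2]) {
        warning("overlapping motion bursts merged")
        merged[last, 2] <- max(merged[last, 2], bm[k, 2])
        merged[last, 3] <- max(merged[last, 3], bm[k, 3])
      } else {
        merged <- rbind(merged, bm[k, , drop = FALSE])
      }
    }
  }
  n <- length(rec$pcg)
  if (is.null(rec$motion)) rec$motion <- numeric(n)
  pcg_scale <- stats::sd(rec$pcg)
  with_seed(seed, {
    for (k in seq_len(nrow(merged))) {
      i0 <- ms_to_idx(merged[k, 1], rec$fs_hz)
      i1 <- min(n, ms_to_idx(merged[k, 2], rec$fs_hz) - 1L)
      idx <- i0:i1
      g <- merged[k, 3]
      # smooth-edged acceleration plateau reaching exactly g
      w <- length(idx)
      edge <- max(2L, as.integer(round(0.05 * w)))
      prof <- rep(1, w)
      ramp <- seq(0, 1, length.out = edge)
      prof[seq_len(edge)] <- ramp
      prof[(w - edge + 1):w] <- rev(ramp)
      rec$motion[idx] <- pmax(rec$motion[idx], g * prof)
      rec$pcg[idx] <- rec$pcg[idx] +
        stats::rnorm(w, 0, 6 * g * max(pcg_scale, 1e-12)) * prof
    }
  })
  rec
}
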