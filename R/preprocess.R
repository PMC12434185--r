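# Preprocessing and device-style quality control: zero-phase ECG bandpass,
# signal quality index (SQI), motion/drift segment rejection, and automatic
# gain calibration of the PCG.

#' Design the ECG bandpass (0.05-150 Hz)
#'
#' Returns the two Butterworth sections used by [bandpass_ecg()]: a 2nd-order
#' 0.05 Hz highpass and a 4th-order 150 Hz lowpass. Both are applied
#' forward-backward, so the effective magnitude response is the square of
#' each section's and the phase is exactly zero.
#'
#' @param fs_hz Sampling rate, Hz (>= 500).
#' @return List with elements `hp` and `lp` (as from [signal::butter()]).
#' @export
ecg_filter_design <- function(fs_hz) {
  stop_if(fs_hz < 500, "fs_hz must be >= 500 Hz")
  stop_if(fs_hz / 2 <= 150, "sampling rate too low for the 150 Hz band edge")
  list(hp = signal::butter(2, 0.05 / (fs_hz / 2), type = "high"),
       lp = signal::butter(4, 150 / (fs_hz / 2), type = "low"))
}

#' Magnitude response of the full (forward-backward) ECG bandpass
#'
#' @param fs_hz Sampling rate, Hz.
#' @param f_hz Frequencies at which to evaluate, Hz.
#' @return Linear gain of the zero-phase cascade at each frequency.
#' @export
ecg_filter_gain <- function(fs_hz, f_hz) {
  d <- ecg_filter_design(fs_hz)
  gain1 <- function(flt, f) {
    z <- exp(-1i * 2 * pi * f / fs_hz)
    abs(vapply(z, function(zz) {
      sum(flt$b * zz^(seq_along(flt$b) - 1)) /
        sum(flt$a * zz^(seq_along(flt$a) - 1))
    }, complex(1)))
  }
  (gain1(d$hp, f_hz) * gain1(d$lp, f_hz))^2
}

#' Zero-phase 0.05-150 Hz ECG bandpass
#'
#' Removes baseline wander below 0.05 Hz and content above 150 Hz without
#' shifting event timing (forward-backward filtering).
#'
#' @param ecg_trace Numeric ECG trace, mV.
#' @param fs_hz Sampling rate, Hz (>= 500).
#' @return Filtered trace.
#' @export
bandpass_ecg <- function(ecg_trace, fs_hz) {
  d <- ecg_filter_design(fs_hz)
  stop_if(length(ecg_trace) < 10 * max(length(d$lp$b), length(d$hp$b)),
          "trace shorter than filter warm-up")
  if (all(ecg_trace == 0)) return(ecg_trace)
  y <- signal::filtfilt(d$hp, ecg_trace)
  signal::filtfilt(d$lp, y)
}

# Provisional per-beat envelope segments for SQI: windows [ref, ref+win_ms)
beat_envelope_matrix <- function(env, fs_hz, beat_refs_ms, win_ms = 600,
                                 n_points = 120) {
  segs <- lapply(beat_refs_ms, function(t0) {
    i0 <- ms_to_idx(t0, fs_hz)
    i1 <- min(length(env), ms_to_idx(t0 + win_ms, fs_hz) - 1L)
    if (i1 - i0 < 10) return(NULL)
    resample_to(env[i0:i1], n_points)
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0) return(NULL)
  do.call(rbind, segs)
}

#' Signal quality index of a PCG recording
#'
#' Per-recording SQI in [0, 1], defined as the mean (over beats) of the
#' positive part of the Pearson correlation between each beat's PCG envelope
#' and the median envelope template of all beats. Self-consistent beats give
#' values near 1; noise-dominated recordings fall well below the 0.8
#' validity threshold.
#'
#' @param pcg_trace Numeric PCG trace (denoised or raw).
#' @param fs_hz Sampling rate, Hz.
#' @param beat_refs_ms Per-beat reference times (QRS onsets), ms.
#' @return SQI in [0, 1]. Fewer than 3 beats yields 0 with a warning.
#' @export
compute_sqi <- function(pcg_trace, fs_hz, beat_refs_ms) {
  if (length(beat_refs_ms) < 3) {
    warning("fewer than 3 beats; SQI set to 0")
    return(0)
  }
  env <- pcg_envelope(pcg_trace, fs_hz)
  m <- beat_envelope_matrix(env, fs_hz, beat_refs_ms)
  if (is.null(m) || nrow(m) < 3) {
    warning("fewer than 3 usable beat windows; SQI set to 0")
    return(0)
  }
  template <- apply(m, 2, stats::median)
  if (stats::sd(template) == 0) return(0)
  r <- apply(m, 1, function(row) {
    if (stats::sd(row) == 0) return(0)
    stats::cor(row, template)
  })
  mean(pmax(r, 0))
}

new_quality_report <- function(sqi, flags, s1_amplitude_cv = NA_real_,
                               gain_applied = 1) {
  valid <- sqi > 0.8 && nrow(flags) == 0
  structure(list(sqi = sqi, valid = valid, segment_flags = flags,
                 s1_amplitude_cv = s1_amplitude_cv,
                 gain_applied = gain_applied),
            class = "acg_quality_report")
}

#' @export
print.acg_quality_report <- function(x, ...) {
  cat(sprintf("<quality report> SQI %.3f, %s, %d flag(s)\n", x$sqi,
              if (x$valid) "valid" else "NOT valid", nrow(x$segment_flags)))
  if (nrow(x$segment_flags) > 0) print(x$segment_flags)
  invisible(x)
}

# contiguous runs where `mask` is TRUE, as [start_ms, end_ms) intervals
mask_to_segments <- function(mask, fs_hz) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_ms = idx_to_ms(starts[keep], fs_hz),
             end_ms = idx_to_ms(ends[keep] + 1L, fs_hz))
}

#' Quality-control screening of a recording
#'
#' Applies the device QC rules: flags every segment where the motion channel
#' exceeds `motion_g` (default 0.5 g); flags the recording when the
#' low-frequency (< 0.5 Hz) ECG envelope amplitude exceeds `drift_mv`
#' (default 1 mV, measured as half the peak-to-peak excursion); computes the
#' SQI against provisional QRS references and flags `low_sqi` when it is at
#' or below `sqi_min` (default 0.8). The report is `valid` only when the SQI
#' clears the threshold and no flags were raised.
#'
#' @param rec An `acg_recording`.
#' @param motion_g,drift_mv,sqi_min QC thresholds.
#' @return An `acg_quality_report`.
#' @export
qc_segments <- function(rec, motion_g = 0.5, drift_mv = 1.0, sqi_min = 0.8) {
  flags <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      reason = character(0))

  if (!is.null(rec$motion) && any(rec$motion > motion_g)) {
    seg <- mask_to_segments(rec$motion > motion_g, rec$fs_hz)
    seg$reason <- "motion"
    flags <- rbind(flags, seg)
  }

  lf <- fft_lowpass(rec$ecg, rec$fs_hz, 0.5, order = 4)
  drift_amp <- (max(lf) - min(lf)) / 2
  if (drift_amp > drift_mv) {
    flags <- rbind(flags, data.frame(start_ms = 0, end_ms = rec$duration_ms,
                                     reason = "drift"))
  }

  ecg_f <- bandpass_ecg(rec$ecg, rec$fs_hz)
  qrs <- detect_qrs(ecg_f, rec$fs_hz)
  sqi <- if (nrow(qrs) >= 3) {
    suppressWarnings(compute_sqi(rec$pcg, rec$fs_hz, qrs$qrs_onset_ms))
  } else 0
  if (sqi <= sqi_min) {
    flags <- rbind(flags, data.frame(start_ms = 0, end_ms = rec$duration_ms,
                                     reason = "low_sqi"))
  }
  new_quality_report(sqi, flags)
}

#' Automatic PCG gain calibration
#'
#' Emulates the device's +/-30% automatic gain adjustment: per-beat S1 peak
#' envelope amplitudes are measured at the beat references, a global gain
#' `target_amp / median(amplitude)` (clamped to `1 +/- gain_limit`) restores
#' the nominal level, and residual per-beat gains (each clamped to the same
#' absolute range) stabilize beat-to-beat amplitude so the post-calibration
#' coefficient of variation stays below `cv_max` when achievable.
#'
#' @param pcg_trace Numeric PCG trace.
#' @param fs_hz Sampling rate, Hz.
#' @param beat_refs_ms QRS-onset reference times, ms (>= 5 beats).
#' @param target_amp Nominal S1 peak envelope amplitude; `NULL` uses the
#'   recording's own median (per-beat stabilization only).
#' @param gain_limit Maximum fractional gain deviation (default 0.30).
#' @param cv_max Target coefficient of variation (default 0.08).
#' @param s1_window_ms Window after each reference searched for the S1 peak.
#' @return List with `trace` (calibrated), `gain_applied` (global gain),
#'   `s1_amplitude_cv` (post-calibration CV), and `limited` (TRUE when the
#'   required gain exceeded the limit, recorded as a warning).
#' @export
gain_calibrate <- function(pcg_trace, fs_hz, beat_refs_ms, target_amp = NULL,
                           gain_limit = 0.30, cv_max = 0.08,
                           s1_window_ms = 250) {
  stop_if(length(beat_refs_ms) < 5, "gain calibration needs >= 5 beats")
  env <- pcg_envelope(pcg_trace, fs_hz)
  amps <- vapply(beat_refs_ms, function(t0) {
    i0 <- ms_to_idx(t0, fs_hz)
    i1 <- min(length(env), ms_to_idx(t0 + s1_window_ms, fs_hz) - 1L)
    max(env[i0:i1])
  }, numeric(1))
  stop_if(any(amps <= 0), "non-positive S1 amplitude in calibration window")

  med <- stats::median(amps)
  if (is.null(target_amp)) target_amp <- med
  lo <- 1 - gain_limit
  hi <- 1 + gain_limit

  g_needed <- target_amp / med
  limited <- g_needed < lo || g_needed > hi
  if (limited) {
    warning(sprintf("required gain %.2f outside +/-%d%% calibration limit",
                    g_needed, round(100 * gain_limit)))
  }
  g_global <- min(max(g_needed, lo), hi)
  if (abs(g_global - 1) < 0.02 && stats::sd(amps) / med < cv_max) {
    g_global <- 1
  }

  # residual per-beat trim, each total gain clamped to the absolute range
  g_beat <- pmin(pmax(target_amp / amps, lo), hi)
  post <- amps * g_beat
  cv <- stats::sd(post) / mean(post)

  # smooth piecewise-linear gain curve through the beat references
  centers <- ms_to_idx(beat_refs_ms + s1_window_ms / 2, fs_hz)
  gcurve <- stats::approx(centers, g_beat, xout = seq_along(pcg_trace),
                          rule = 2)$y
  list(trace = pcg_trace * gcurve, gain_applied = g_global,
       s1_amplitude_cv = cv, limited = limited)
}
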