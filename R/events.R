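# Event detection: QRS complexes on the ECG (derivative-square-integrate
# detector with onset backtracking) and S1/S2 heart sounds on the PCG
# (physiologic gates after each QRS onset; peak/onset/end landmarks from the
# denoised envelope; per-beat validation by DTW alignment of the beat's MFCC
# segment against the recording's own median-beat template).

#' Detect QRS complexes
#'
#' Pan-Tompkins-style detector: 5-25 Hz zero-phase bandpass, derivative,
#' squaring, 150 ms moving-window integration, adaptive threshold with a
#' 300 ms refractory period. The R peak is the absolute extremum of the
#' input trace near each integrated peak; the onset is backtracked on the
#' short-window RMS of the trace's slope, from the steepest point of the
#' QRS to the last sample below 1.5% of the beat's maximum slope (with a
#' noise-adaptive floor).
#'
#' @param ecg_trace Preprocessed ECG trace, mV.
#' @param fs_hz Sampling rate, Hz.
#' @return Data frame with `qrs_onset_ms`, `qrs_peak_ms`,
#'   `qrs_peak_amplitude_mv`, one row per detected beat (0 rows with a
#'   warning when nothing is found).
#' @export
detect_qrs <- function(ecg_trace, fs_hz) {
  empty <- data.frame(qrs_onset_ms = numeric(0), qrs_peak_ms = numeric(0),
                      qrs_peak_amplitude_mv = numeric(0))
  if (all(ecg_trace == 0)) {
    warning("no QRS detections")
    return(empty)
  }
  bp <- signal::filtfilt(signal::butter(3, c(5, 25) / (fs_hz / 2)), ecg_trace)
  dx <- c(0, diff(bp)) * fs_hz
  sq <- dx^2
  win <- as.integer(round(0.150 * fs_hz))
  integ <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0

  thr <- 0.25 * stats::quantile(integ, 0.995, names = FALSE)
  if (thr <= 0) {
    warning("no QRS detections")
    return(empty)
  }
  refractory <- as.integer(round(0.300 * fs_hz))
  above <- integ > thr
  peaks <- integer(0)
  i <- 1L
  n <- length(integ)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1L
      seg_peak <- i - 1L + which.max(integ[i:j])
      if (length(peaks) == 0 || seg_peak - peaks[length(peaks)] > refractory) {
        peaks <- c(peaks, seg_peak)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(peaks) == 0) {
    warning("no QRS detections")
    return(empty)
  }

  half <- as.integer(round(0.08 * fs_hz))
  # QRS onset is backtracked on the trace's slope: baseline offsets and
  # filter pedestals have negligible derivative, while the QRS deflection
  # slope dominates everything else in the beat. The threshold floor adapts
  # to the trace-wide slope noise so clean recordings resolve the faint
  # Q-wave onset while noisy ones fall back to the upstroke emergence.
  dslope <- abs(c(0, diff(ecg_trace))) * fs_hz / 1000   # mV per ms
  # short RMS so stationary points inside the QRS (e.g. the Q trough) do
  # not read as sub-threshold dips
  swin <- max(3L, as.integer(round(0.008 * fs_hz)))
  sma <- as.numeric(stats::filter(dslope^2, rep(1 / swin, swin), sides = 1))
  sma[is.na(sma)] <- 0
  slope <- sqrt(pmax(sma, 0))
  slope_floor <- 3 * stats::quantile(slope, 0.25, names = FALSE)
  out <- lapply(peaks, function(p) {
    i0 <- max(1L, p - half); i1 <- min(n, p + half)
    rp <- i0 - 1L + which.max(abs(ecg_trace[i0:i1]))
    amp <- abs(ecg_trace[rp])
    # backtrack from the steepest point of the QRS (not the apex, where the
    # slope vanishes) to the last sample below threshold
    back <- max(1L, rp - as.integer(round(0.08 * fs_hz)))
    win <- slope[back:rp]
    ms_i <- which.max(win)
    thr <- max(0.015 * win[ms_i], slope_floor)
    below <- which(win[seq_len(ms_i)] < thr)
    onset <- if (length(below) > 0) back - 1L + below[length(below)] else back
    # refine: the RMS needs a few samples to accumulate threshold energy,
    # so snap to the first raw-slope sample above threshold nearby (clean
    # recordings only; in noise no single raw sample clears the floor)
    w0 <- max(back, onset - swin)
    w1 <- min(rp, onset + swin)
    cand <- which(dslope[w0:w1] >= thr)
    if (length(cand) > 0) onset <- w0 - 1L + cand[1]
    c(onset, rp, amp)
  })
  out <- do.call(rbind, out)
  out <- out[order(out[, 1]), , drop = FALSE]
  # enforce strictly increasing onsets (drop duplicates from split peaks)
  keep <- c(TRUE, diff(out[, 1]) > 0)
  out <- out[keep, , drop = FALSE]
  data.frame(qrs_onset_ms = idx_to_ms(out[, 1], fs_hz),
             qrs_peak_ms = idx_to_ms(out[, 2], fs_hz),
             qrs_peak_amplitude_mv = out[, 3])
}

# landmark helper: envelope peak inside [t0, t1) plus 10%-of-peak bounds
envelope_landmarks <- function(env, fs_hz, t0, t1, frac = 0.10) {
  i0 <- ms_to_idx(t0, fs_hz)
  i1 <- min(length(env), ms_to_idx(t1, fs_hz) - 1L)
  if (i1 <= i0) return(NULL)
  pk <- i0 - 1L + which.max(env[i0:i1])
  pk_val <- env[pk]
  if (pk_val <= 0) return(NULL)
  thr <- frac * pk_val
  # last sample at/above threshold moving forward from the peak
  fw <- env[pk:i1] >= thr
  endi <- if (all(fw)) i1 else pk - 1L + which(!fw)[1] - 1L
  bw <- env[i0:pk] >= thr
  starti <- if (all(bw)) i0 else pk + 1L - (which(!rev(bw))[1] - 1L)
  list(peak_idx = pk, peak_ms = idx_to_ms(pk, fs_hz), peak_val = pk_val,
       onset_ms = idx_to_ms(starti, fs_hz), end_ms = idx_to_ms(endi, fs_hz))
}

#' Detect S1 and S2 heart sounds
#'
#' For each QRS reference, S1 is sought in the gate `[onset, onset+200)` ms
#' and S2 in `[onset+200, onset+600)` ms (clipped at the next beat). Peak
#' times come from the denoised PCG envelope; S1/S2 onset and end use the
#' 10%-of-peak envelope criterion. Each beat's MFCC segment is then aligned
#' by DTW (z-scored, Sakoe-Chiba band) to the recording's median-beat
#' template; beats whose normalized alignment cost exceeds
#' `dtw_cost_max` are marked invalid, as are beats with a missing or
#' mis-ordered S1/S2.
#'
#' @param mfcc An `acg_mfcc` for the denoised PCG.
#' @param pcg_env Envelope of the denoised PCG (from [pcg_envelope()]).
#' @param qrs_refs Data frame from [detect_qrs()].
#' @param fs_hz Sampling rate of the envelope, Hz.
#' @param s1_gate_ms,s2_gate_ms Search gates relative to QRS onset, ms.
#' @param dtw_cost_max Normalized DTW cost above which a beat is rejected
#'   (calibrated on clean simulated recordings).
#' @param s2_min_rel Minimum S2 peak envelope relative to the across-beat
#'   median, below which the beat is rejected as `s2-not-found`.
#' @return Data frame of class `acg_beat_events`: per-beat event times (ms),
#'   amplitudes, `valid` flag and `rejection_reason`.
#' @export
detect_heart_sounds <- function(mfcc, pcg_env, qrs_refs, fs_hz,
                                s1_gate_ms = c(0, 200),
                                s2_gate_ms = c(200, 600),
                                dtw_cost_max = 3.5, s2_min_rel = 0.15) {
  stop_if(nrow(qrs_refs) < 3, "need >= 3 QRS references")
  onsets <- qrs_refs$qrs_onset_ms
  n_beats <- length(onsets)
  next_onset <- c(onsets[-1], Inf)

  rows <- vector("list", n_beats)
  for (k in seq_len(n_beats)) {
    o <- onsets[k]
    row <- list(beat = k, qrs_onset_ms = o,
                qrs_peak_ms = qrs_refs$qrs_peak_ms[k],
                qrs_peak_amplitude_mv = qrs_refs$qrs_peak_amplitude_mv[k],
                s1_onset_ms = NA_real_, s1_peak_ms = NA_real_,
                s1_end_ms = NA_real_, s1_peak_amplitude = NA_real_,
                s2_onset_ms = NA_real_, s2_peak_ms = NA_real_,
                s2_peak_amplitude = NA_real_,
                valid = TRUE, rejection_reason = NA_character_)

    s1 <- envelope_landmarks(pcg_env, fs_hz, o + s1_gate_ms[1],
                             min(o + s1_gate_ms[2], next_onset[k]))
    if (is.null(s1)) {
      row$valid <- FALSE; row$rejection_reason <- "s1-not-found"
      rows[[k]] <- row; next
    }
    row$s1_onset_ms <- s1$onset_ms
    row$s1_peak_ms <- s1$peak_ms
    row$s1_end_ms <- s1$end_ms
    row$s1_peak_amplitude <- s1$peak_val

    s2 <- envelope_landmarks(pcg_env, fs_hz,
                             max(o + s2_gate_ms[1], s1$end_ms),
                             min(o + s2_gate_ms[2], next_onset[k]))
    if (is.null(s2)) {
      row$valid <- FALSE; row$rejection_reason <- "s2-not-found"
      rows[[k]] <- row; next
    }
    row$s2_onset_ms <- s2$onset_ms
    row$s2_peak_ms <- s2$peak_ms
    row$s2_peak_amplitude <- s2$peak_val

    ok <- o < row$s1_onset_ms && row$s1_onset_ms < row$s1_peak_ms &&
      row$s1_peak_ms < row$s1_end_ms && row$s1_end_ms < row$s2_peak_ms
    if (!ok) {
      row$valid <- FALSE; row$rejection_reason <- "ordering"
    }
    rows[[k]] <- row
  }
  beats <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))

  # relative S2 floor: an absent S2 leaves only the noise floor in its gate
  med_s2 <- stats::median(beats$s2_peak_amplitude, na.rm = TRUE)
  if (is.finite(med_s2) && med_s2 > 0) {
    weak <- !is.na(beats$s2_peak_amplitude) &
      beats$s2_peak_amplitude < s2_min_rel * med_s2 & beats$valid
    beats$valid[weak] <- FALSE
    beats$rejection_reason[weak] <- "s2-not-found"
  }

  # DTW validation against the recording's own median-beat MFCC template
  segs <- beat_mfcc_segments(mfcc, onsets, next_onset, s2_gate_ms[2])
  usable <- which(!vapply(segs, is.null, logical(1)))
  if (length(usable) >= 3) {
    len <- min(vapply(segs[usable], nrow, integer(1)))
    stack <- vapply(segs[usable], function(s) zscore_frames(s[seq_len(len), ,
                                                              drop = FALSE]),
                    matrix(0, len, ncol(segs[[usable[1]]])))
    template <- apply(stack, c(1, 2), stats::median)
    for (k in usable) {
      cost <- dtw_distance(zscore_frames(segs[[k]]), template)
      if (cost > dtw_cost_max && beats$valid[k]) {
        beats$valid[k] <- FALSE
        beats$rejection_reason[k] <- "poor-template-match"
      }
    }
  }

  if (!any(beats$valid)) warning("no valid beats in recording")
  class(beats) <- c("acg_beat_events", class(beats))
  beats
}

# per-beat MFCC frame segments covering [onset, onset + win) clipped at the
# next onset
beat_mfcc_segments <- function(mfcc, onsets, next_onset, win_ms) {
  ft <- mfcc$frame_times_ms
  lapply(seq_along(onsets), function(k) {
    sel <- ft >= onsets[k] & ft < min(onsets[k] + win_ms, next_onset[k])
    if (sum(sel) < 5) return(NULL)
    mfcc$coefficients[sel, , drop = FALSE]
  })
}
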