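# Pipeline configuration and the end-to-end per-recording chain:
# preprocess -> QC -> QRS -> MFCC -> S1/S2 detection -> intervals.

#' Pipeline configuration
#'
#' Collects every tunable threshold in one serializable object. QC defaults
#' are the device rules: SQI > 0.8 for validity, motion rejection above
#' 0.5 g, baseline-drift rejection above 1 mV, gain adjustment within
#' +/-30%, S1/S2 amplitude stability target CV < 8%.
#'
#' @param fs_hz Working sampling rate, Hz.
#' @param sqi_min,motion_g,drift_mv,gain_limit,cv_max QC thresholds.
#' @param s1_gate_ms,s2_gate_ms Heart-sound search gates after QRS onset, ms.
#' @param frame_len_ms,hop_ms,n_mfcc MFCC settings.
#' @param dtw_cost_max Beat-rejection threshold on normalized DTW cost.
#' @param t_test `"welch"` or `"pooled"` for group comparisons.
#' @param alpha_screen Univariate screening threshold (default 0.1).
#' @param alpha_enter Stepwise entry threshold (default 0.05).
#' @param seed Default seed for simulation subcommands.
#' @return An `acg_config` list.
#' @export
pipeline_config <- function(fs_hz = 2000, sqi_min = 0.8, motion_g = 0.5,
                            drift_mv = 1.0, gain_limit = 0.3, cv_max = 0.08,
                            s1_gate_ms = c(0, 200), s2_gate_ms = c(200, 600),
                            frame_len_ms = 25, hop_ms = 10, n_mfcc = 40,
                            dtw_cost_max = 3.5,
                            t_test = c("welch", "pooled"),
                            alpha_screen = 0.1, alpha_enter = 0.05,
                            seed = 1L) {
  t_test <- match.arg(t_test)
  stop_if(sqi_min <= 0 || motion_g <= 0 || drift_mv <= 0 || gain_limit <= 0 ||
            cv_max <= 0, "thresholds must be positive")
  structure(list(fs_hz = fs_hz, sqi_min = sqi_min, motion_g = motion_g,
                 drift_mv = drift_mv, gain_limit = gain_limit,
                 cv_max = cv_max, s1_gate_ms = s1_gate_ms,
                 s2_gate_ms = s2_gate_ms, frame_len_ms = frame_len_ms,
                 hop_ms = hop_ms, n_mfcc = n_mfcc,
                 dtw_cost_max = dtw_cost_max, t_test = t_test,
                 alpha_screen = alpha_screen, alpha_enter = alpha_enter,
                 seed = as.integer(seed)),
            class = "acg_config")
}

#' Process one recording end to end
#'
#' Runs the full chain on a synchronized ECG-PCG recording: ECG bandpass,
#' PCG wavelet-packet denoising, quality control, QRS detection, MFCC
#' extraction, S1/S2 detection with DTW validation, per-beat intervals and
#' per-recording aggregation. Beats overlapping motion-flagged segments are
#' invalidated before aggregation.
#'
#' @param rec An `acg_recording`.
#' @param config An [pipeline_config()].
#' @return List with `params` (`acg_params`), `beats`, `qc`, `qrs`.
#' @export
process_recording <- function(rec, config = pipeline_config(fs_hz = rec$fs_hz)) {
  fs <- rec$fs_hz
  ecg_f <- bandpass_ecg(rec$ecg, fs)
  pcg_d <- denoise_pcg(rec$pcg, fs)
  qc <- qc_segments(rec, motion_g = config$motion_g,
                    drift_mv = config$drift_mv, sqi_min = config$sqi_min)
  qrs <- detect_qrs(ecg_f, fs)
  if (nrow(qrs) < 3) {
    beats <- data.frame()
    params <- aggregate_recording(
      data.frame(valid = logical(0), qrs_onset_ms = numeric(0)), qc)
    return(list(params = params, beats = beats, qc = qc, qrs = qrs))
  }
  mf <- extract_mfcc(pcg_d, fs, frame_len_ms = config$frame_len_ms,
                     hop_ms = config$hop_ms, n_mfcc = config$n_mfcc)
  env <- pcg_envelope(pcg_d, fs)
  beats <- detect_heart_sounds(mf, env, qrs, fs,
                               s1_gate_ms = config$s1_gate_ms,
                               s2_gate_ms = config$s2_gate_ms,
                               dtw_cost_max = config$dtw_cost_max)
  beats <- invalidate_motion_beats(beats, qc)
  beats <- beat_params(beats)
  params <- aggregate_recording(beats, qc)
  list(params = params, beats = beats, qc = qc, qrs = qrs)
}

# invalidate beats whose systole overlaps a motion-flagged segment
invalidate_motion_beats <- function(beats, qc) {
  fl <- qc$segment_flags
  fl <- fl[fl$reason == "motion", , drop = FALSE]
  if (nrow(fl) == 0 || nrow(beats) == 0) return(beats)
  for (k in seq_len(nrow(beats))) {
    if (!beats$valid[k]) next
    b0 <- beats$qrs_onset_ms[k]
    b1 <- if (is.finite(beats$s2_peak_ms[k])) beats$s2_peak_ms[k] + 100
          else b0 + 700
    hit <- any(fl$start_ms < b1 & fl$end_ms > b0)
    if (hit) {
      beats$valid[k] <- FALSE
      beats$rejection_reason[k] <- "motion"
    }
  }
  beats
}

#' Cohort-level diagnostic analysis
#'
#' Reproduces the diagnostic-model layer on a cohort table: univariate
#' screening (p < `alpha_screen`), forward-stepwise logistic regression over
#' the survivors, ROC analyses for LVET alone and for the fitted model's
#' predicted probabilities, and a DeLong comparison between them.
#'
#' @param cohort Cohort data frame (`group` + predictors).
#' @param config An [pipeline_config()].
#' @param candidates Candidate predictors for screening.
#' @return List with `screen`, `model`, `roc_lvet`, `roc_model`, `delong`.
#' @export
analyze_cohort <- function(cohort, config = pipeline_config(),
                           candidates = c("lvet_ms", "q2s2max",
                                          "htn_history", "hr_bpm")) {
  candidates <- intersect(candidates, names(cohort))
  screen <- univariate_screen(cohort, candidates,
                              alpha_in = config$alpha_screen)
  selected <- attr(screen, "selected")
  model <- if (length(selected) > 0) {
    fit_logistic_forward(cohort, selected, alpha_enter = config$alpha_enter)
  } else {
    NULL
  }
  roc_lvet <- roc_analysis(cohort$lvet_ms, cohort$group, "greater")
  roc_model <- if (!is.null(model) && length(model$variables) > 0) {
    roc_analysis(model$probabilities, cohort$group, "greater")
  } else {
    NULL
  }
  dl <- if (!is.null(roc_model)) {
    delong_test(model$probabilities, cohort$lvet_ms,
                outcome_to_binary(cohort$group))
  } else {
    NULL
  }
  list(screen = screen, model = model, roc_lvet = roc_lvet,
       roc_model = roc_model, delong = dl)
}
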