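# Systolic time intervals and amplitude indices from detected beat events:
# LVET (end of S1 to S2 peak), EMAT (QRS onset to S1 peak intensity),
# LVST (S1 peak to S2 peak), Q2S2Max (S2 peak amplitude / QRS amplitude,
# with the raw S2 amplitude also exposed), plus per-recording aggregation.

#' Per-beat left ventricular ejection time
#'
#' `lvet_ms = s2_peak_ms - s1_end_ms`. Non-positive values are
#' non-physiologic and return `NA` (callers invalidate the beat).
#'
#' @param beat One row of an `acg_beat_events` data frame (or a list with
#'   the same fields).
#' @return LVET in ms, or `NA_real_`.
#' @export
compute_lvet <- function(beat) {
  v <- beat$s2_peak_ms - beat$s1_end_ms
  if (!is.finite(v) || v <= 0) return(NA_real_)
  v
}

#' Per-beat electromechanical activation time
#'
#' `emat_ms = s1_peak_ms - qrs_onset_ms`; non-positive values return `NA`.
#'
#' @inheritParams compute_lvet
#' @return EMAT in ms, or `NA_real_`.
#' @export
compute_emat <- function(beat) {
  v <- beat$s1_peak_ms - beat$qrs_onset_ms
  if (!is.finite(v) || v <= 0) return(NA_real_)
  v
}

#' Per-beat left ventricular systolic time
#'
#' `lvst_ms = s2_peak_ms - s1_peak_ms` (S1 peak to S2 peak); always at least
#' the beat's LVET on ordered events, since the S1 peak precedes the S1 end.
#'
#' @inheritParams compute_lvet
#' @return LVST in ms, or `NA_real_`.
#' @export
compute_lvst <- function(beat) {
  v <- beat$s2_peak_ms - beat$s1_peak_ms
  if (!is.finite(v) || v <= 0) return(NA_real_)
  v
}

#' Per-beat second-heart-sound amplitude index (Q2S2Max)
#'
#' Ratio of the S2 peak amplitude to the QRS peak amplitude (dimensionless);
#' the raw S2 peak amplitude is returned alongside, since device reports
#' print the amplitude itself.
#'
#' @inheritParams compute_lvet
#' @return List with `ratio` and `raw`; both `NA` when the QRS amplitude is
#'   not positive.
#' @export
compute_q2s2max <- function(beat) {
  if (!is.finite(beat$qrs_peak_amplitude_mv) ||
      beat$qrs_peak_amplitude_mv <= 0 ||
      !is.finite(beat$s2_peak_amplitude)) {
    return(list(ratio = NA_real_, raw = NA_real_))
  }
  list(ratio = beat$s2_peak_amplitude / beat$qrs_peak_amplitude_mv,
       raw = beat$s2_peak_amplitude)
}

#' Per-beat acoustic parameters from detected events
#'
#' Applies the interval definitions to every beat, invalidating beats with
#' non-physiologic values (`non-physiologic-lvet`, `non-physiologic-emat`,
#' `zero-qrs-amplitude`), and appends the beat-to-beat RR interval.
#'
#' @param beats An `acg_beat_events` data frame.
#' @return The data frame with columns `lvet_ms`, `emat_ms`, `lvst_ms`,
#'   `q2s2max_ratio`, `q2s2_amplitude_raw`, `rr_ms` added and validity
#'   updated.
#' @export
beat_params <- function(beats) {
  n <- nrow(beats)
  beats$lvet_ms <- NA_real_
  beats$emat_ms <- NA_real_
  beats$lvst_ms <- NA_real_
  beats$q2s2max_ratio <- NA_real_
  beats$q2s2_amplitude_raw <- NA_real_
  beats$rr_ms <- c(diff(beats$qrs_onset_ms), NA_real_)
  for (k in seq_len(n)) {
    if (!beats$valid[k]) next
    b <- beats[k, ]
    lvet <- compute_lvet(b)
    if (is.na(lvet)) {
      beats$valid[k] <- FALSE
      beats$rejection_reason[k] <- "non-physiologic-lvet"
      next
    }
    emat <- compute_emat(b)
    if (is.na(emat)) {
      beats$valid[k] <- FALSE
      beats$rejection_reason[k] <- "non-physiologic-emat"
      next
    }
    q2 <- compute_q2s2max(b)
    if (is.na(q2$ratio)) {
      beats$valid[k] <- FALSE
      beats$rejection_reason[k] <- "zero-qrs-amplitude"
      next
    }
    beats$lvet_ms[k] <- lvet
    beats$emat_ms[k] <- emat
    beats$lvst_ms[k] <- compute_lvst(b)
    beats$q2s2max_ratio[k] <- q2$ratio
    beats$q2s2_amplitude_raw[k] <- q2$raw
  }
  beats
}

#' Per-recording summary of acoustic parameters
#'
#' Summarizes valid beats with the median (headline statistic, robust to
#' residual artifact beats) and the mean. Heart rate is `60000 / median RR`.
#' The summary is marked low-confidence when fewer than `min_beats` valid
#' beats remain or the QC report is not valid.
#'
#' @param beats Output of [beat_params()].
#' @param qc Optional `acg_quality_report`.
#' @param min_beats Minimum valid beats for a headline summary (default 5).
#' @return An `acg_params` object: per-parameter `median` and `mean`,
#'   `n_valid_beats`, `heart_rate_bpm`, `low_confidence` (+ `reason`), and
#'   the per-beat table.
#' @export
aggregate_recording <- function(beats, qc = NULL, min_beats = 5) {
  vb <- beats[beats$valid, , drop = FALSE]
  pars <- c("lvet_ms", "emat_ms", "lvst_ms", "q2s2max_ratio",
            "q2s2_amplitude_raw")
  if (nrow(vb) == 0) {
    return(structure(list(median = NULL, mean = NULL, n_valid_beats = 0L,
                          heart_rate_bpm = NA_real_, low_confidence = TRUE,
                          reason = "no valid beats", beats = beats),
                     class = "acg_params"))
  }
  med <- vapply(pars, function(p) stats::median(vb[[p]], na.rm = TRUE),
                numeric(1))
  mn <- vapply(pars, function(p) mean(vb[[p]], na.rm = TRUE), numeric(1))
  rr <- stats::median(vb$rr_ms, na.rm = TRUE)
  hr <- if (is.finite(rr) && rr > 0) 60000 / rr else NA_real_
  low <- nrow(vb) < min_beats || (!is.null(qc) && !qc$valid)
  reason <- if (!low) {
    NA_character_
  } else if (nrow(vb) < min_beats) {
    sprintf("only %d valid beats", nrow(vb))
  } else {
    "quality control failed"
  }
  structure(list(median = as.list(med), mean = as.list(mn),
                 n_valid_beats = nrow(vb), heart_rate_bpm = hr,
                 low_confidence = low, reason = reason, beats = beats),
            class = "acg_params")
}

#' @export
print.acg_params <- function(x, ...) {
  if (x$n_valid_beats == 0) {
    cat("<acoustic params> no valid beats:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<acoustic params> %d valid beats, HR %.1f bpm%s\n",
    x$n_valid_beats, x$heart_rate_bpm,
    if (x$low_confidence) sprintf(" [low confidence: %s]", x$reason) else ""))
  cat(sprintf("  LVET %.1f ms | EMAT %.1f ms | LVST %.1f ms | Q2S2Max %.3f (median)\n",
              x$median$lvet_ms, x$median$emat_ms, x$median$lvst_ms,
              x$median$q2s2max_ratio))
  invisible(x)
}
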