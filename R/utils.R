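# Shared helpers: local RNG, time/index conversion, envelopes, intervals.
# Conventions used throughout the package: times are milliseconds from
# recording start, sample indices are 0-based, windows are half-open
# [start, end).

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards, so simulator calls are reproducible without disturbing
#' the session.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# ms -> 1-based sample index (sample i covers [i*dt, (i+1)*dt), 0-based i)
ms_to_idx <- function(t_ms, fs_hz) {
  as.integer(floor(t_ms * fs_hz / 1000)) + 1L
}

idx_to_ms <- function(idx, fs_hz) {
  (idx - 1L) * 1000 / fs_hz
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' Zero-phase FFT-domain lowpass
#'
#' Applies a squared Butterworth magnitude response of the given order in the
#' frequency domain. Exactly zero phase; used for envelopes and drift
#' estimation where timing fidelity matters more than causality.
#'
#' @param x Numeric trace.
#' @param fs_hz Sampling rate (Hz).
#' @param cutoff_hz Cutoff frequency (Hz).
#' @param order Butterworth order of the magnitude prototype.
#' @return Filtered trace, same length as `x`.
#' @keywords internal
fft_lowpass <- function(x, fs_hz, cutoff_hz, order = 4) {
  n <- length(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs_hz / n
  h <- 1 / sqrt(1 + (abs(f) / cutoff_hz)^(2 * order))
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

#' Amplitude envelope of a phonocardiogram trace
#'
#' Rectifies the trace and smooths with a zero-phase lowpass, giving a
#' non-negative envelope whose peaks align with burst centres.
#'
#' @param x Numeric PCG trace.
#' @param fs_hz Sampling rate (Hz).
#' @param cutoff_hz Envelope smoothing cutoff; default 30 Hz (suppresses the
#'   rectified-carrier ripple of both heart sounds while keeping the burst
#'   edges sharp enough for the 10%-of-peak landmark rules).
#' @return Non-negative envelope, same length as `x`.
#' @export
pcg_envelope <- function(x, fs_hz, cutoff_hz = 30) {
  pmax(fft_lowpass(abs(x), fs_hz, cutoff_hz, order = 4), 0)
}

# Merge overlapping/adjacent [start, end) intervals given as a 2-col matrix.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (k in 2:nrow(iv)) {
      last <- nrow(out)
      if (iv[k, 1] <= out[last, 2]) {
        out[last, 2] <- max(out[last, 2], iv[k, 2])
      } else {
        out <- rbind(out, iv[k, , drop = FALSE])
      }
    }
  }
  out
}

# Linear resample of a vector to n points (for beat-template comparison).
resample_to <- function(x, n) {
  if (length(x) == n) return(x)
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n))$y
}

# Signal-to-noise ratio in dB of `x` against clean reference `ref`.
snr_db <- function(x, ref) {
  10 * log10(sum(ref^2) / sum((x - ref)^2))
}
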