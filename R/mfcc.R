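# Mel-frequency cepstral coefficients for PCG frames: Hamming window,
# power spectrum, triangular mel filterbank over the heart-sound band,
# log energies, orthonormal DCT-II.

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank: rows = filters, cols = FFT bins (0..nfft/2)
mel_filterbank <- function(n_mels, nfft, fs_hz, fmin, fmax) {
  mels <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  fpts <- mel_to_hz(mels)
  bins_hz <- (0:(nfft %/% 2)) * fs_hz / nfft
  fb <- matrix(0, n_mels, length(bins_hz))
  for (j in seq_len(n_mels)) {
    left <- fpts[j]; center <- fpts[j + 1]; right <- fpts[j + 2]
    up <- (bins_hz - left) / (center - left)
    down <- (right - bins_hz) / (right - center)
    fb[j, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# orthonormal DCT-II matrix (n_out x n_in)
dct2_matrix <- function(n_out, n_in) {
  m <- outer(0:(n_out - 1), 0:(n_in - 1), function(k, j) {
    cos(pi * k * (2 * j + 1) / (2 * n_in))
  })
  m * sqrt(2 / n_in)
  # first row scaling to make the transform orthonormal
}

#' Extract MFCC frames from a PCG trace
#'
#' Frames the trace (Hamming window, no padding: the last partial frame is
#' dropped), computes the power spectrum per frame, applies a triangular mel
#' filterbank over `fmin`-`fmax`, takes log energies and an orthonormal
#' DCT-II, keeping `n_mfcc` coefficients per frame.
#'
#' @param pcg_trace Numeric (denoised) PCG trace.
#' @param fs_hz Sampling rate, Hz.
#' @param frame_len_ms Frame length, ms (default 25).
#' @param hop_ms Frame hop, ms (default 10).
#' @param n_mfcc Coefficients per frame (default 40).
#' @param n_mels Mel filters (default 60; must be >= `n_mfcc`).
#' @param fmin,fmax Filterbank band edges, Hz (default 20-1000, the PCG
#'   acquisition band).
#' @return An `acg_mfcc` object: list with `coefficients` (frames x n_mfcc
#'   matrix), `frame_times_ms` (frame start times), `frame_len_ms`, `hop_ms`.
#' @export
extract_mfcc <- function(pcg_trace, fs_hz, frame_len_ms = 25, hop_ms = 10,
                         n_mfcc = 40, n_mels = 60, fmin = 20, fmax = 1000) {
  stop_if(n_mels < n_mfcc, "n_mels must be >= n_mfcc")
  fmax <- min(fmax, fs_hz / 2)
  frame_len <- as.integer(round(frame_len_ms * fs_hz / 1000))
  hop <- as.integer(round(hop_ms * fs_hz / 1000))
  n <- length(pcg_trace)
  stop_if(frame_len > n, "frame longer than trace")
  n_frames <- (n - frame_len) %/% hop + 1L

  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(frame_len), starts, `+`)   # frame_len x n_frames
  frames <- matrix(pcg_trace[idx], nrow = frame_len)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(frame_len) - 1) / (frame_len - 1))
  frames <- frames * w

  nfft <- 2^ceiling(log2(frame_len))
  if (nfft > frame_len) {
    frames <- rbind(frames, matrix(0, nfft - frame_len, n_frames))
  }
  spec <- Mod(stats::mvfft(frames))^2
  spec <- spec[seq_len(nfft %/% 2 + 1), , drop = FALSE]

  fb <- mel_filterbank(n_mels, nfft, fs_hz, fmin, fmax)
  loge <- log(fb %*% spec + 1e-12)                # n_mels x n_frames
  dct <- dct2_matrix(n_mfcc, n_mels)
  dct[1, ] <- dct[1, ] / sqrt(2)
  cc <- t(dct %*% loge)                           # n_frames x n_mfcc

  structure(list(coefficients = cc,
                 frame_times_ms = starts * 1000 / fs_hz,
                 frame_len_ms = frame_len_ms, hop_ms = hop_ms,
                 fs_hz = fs_hz),
            class = "acg_mfcc")
}

#' @export
print.acg_mfcc <- function(x, ...) {
  cat(sprintf("<mfcc> %d frames x %d coefficients (%g ms frames, %g ms hop)\n",
              nrow(x$coefficients), ncol(x$coefficients),
              x$frame_len_ms, x$hop_ms))
  invisible(x)
}
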