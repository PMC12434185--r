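# Daubechies-6 wavelet-packet denoising. Implemented as a periodized
# orthonormal two-channel filter bank applied recursively to depth `depth`
# (full packet tree), with soft universal thresholding per terminal node.
# Analysis rows are circular shifts by 2 of (h, g); synthesis is the
# transpose, so reconstruction is exact to machine precision.

# db6 orthonormal scaling filter (12 taps, sums to sqrt(2))
DB6_H <- rev(c(-0.0010773010853084796, 0.004777257510945511,
               0.0005538422011614961, -0.03158203931748603,
               0.027522865530305727, 0.09750160558732304,
               -0.12976686756726194, -0.22626469396543983,
               0.31525035170919763, 0.7511339080210954,
               0.49462389039845306, 0.11154074335010947))
DB6_G <- (-1)^(0:11) * rev(DB6_H)

# one analysis step: circular correlation with f, then dyadic downsample
wp_analyze1 <- function(x, f) {
  n <- length(x)
  fp <- c(f, rep(0, n - length(f)))
  y <- Re(stats::fft(stats::fft(x) * Conj(stats::fft(fp)), inverse = TRUE)) / n
  y[seq(1, n, by = 2)]
}

# one synthesis step: dyadic upsample, then circular convolution with f
wp_synthesize1 <- function(a, f, n) {
  ua <- numeric(n)
  ua[seq(1, n, by = 2)] <- a
  fp <- c(f, rep(0, n - length(f)))
  Re(stats::fft(stats::fft(ua) * stats::fft(fp), inverse = TRUE)) / n
}

#' Full wavelet-packet decomposition (db6, periodized)
#'
#' @param x Numeric trace; length must be a multiple of `2^depth` and at
#'   least `2^depth` times the filter support.
#' @param depth Tree depth (default 5, giving 32 terminal nodes).
#' @return List of `2^depth` coefficient vectors (natural/Paley order).
#' @keywords internal
wp_decompose <- function(x, depth = 5) {
  nodes <- list(x)
  for (lev in seq_len(depth)) {
    nxt <- vector("list", 2 * length(nodes))
    for (j in seq_along(nodes)) {
      nxt[[2 * j - 1]] <- wp_analyze1(nodes[[j]], DB6_H)
      nxt[[2 * j]] <- wp_analyze1(nodes[[j]], DB6_G)
    }
    nodes <- nxt
  }
  nodes
}

#' Reconstruct a trace from wavelet-packet coefficients
#' @keywords internal
wp_reconstruct <- function(nodes, depth = 5) {
  for (lev in seq_len(depth)) {
    half <- length(nodes) / 2
    nxt <- vector("list", half)
    for (j in seq_len(half)) {
      n_out <- 2 * length(nodes[[2 * j - 1]])
      nxt[[j]] <- wp_synthesize1(nodes[[2 * j - 1]], DB6_H, n_out) +
        wp_synthesize1(nodes[[2 * j]], DB6_G, n_out)
    }
    nodes <- nxt
  }
  nodes[[1]]
}

#' Wavelet-packet denoising of a phonocardiogram trace
#'
#' Decomposes the trace with a depth-`depth` Daubechies-6 wavelet-packet
#' tree and applies soft universal thresholding independently in each
#' terminal node: threshold `sigma * sqrt(2 log m)` with `sigma` the node's
#' median absolute deviation / 0.6745 estimate of the noise scale. The trace
#' is zero-padded to a multiple of `2^depth` and trimmed after
#' reconstruction.
#'
#' @param pcg_trace Numeric PCG trace.
#' @param fs_hz Sampling rate, Hz (recorded for interface symmetry; the
#'   transform itself is rate-agnostic).
#' @param depth Packet-tree depth, default 5.
#' @return Denoised trace, same length as the input.
#' @examples
#' x <- sin(2 * pi * 40 * seq(0, 1, by = 1/2000))
#' y <- denoise_pcg(x + rnorm(length(x), 0, 0.5), fs_hz = 2000)
#' @export
denoise_pcg <- function(pcg_trace, fs_hz, depth = 5) {
  n0 <- length(pcg_trace)
  block <- 2^depth
  stop_if(n0 < block * length(DB6_H),
          "trace shorter than one wavelet-packet decomposition block")
  if (all(pcg_trace == 0)) return(pcg_trace)
  pad <- (block - n0 %% block) %% block
  x <- c(pcg_trace, rep(0, pad))
  nodes <- wp_decompose(x, depth)
  nodes <- lapply(nodes, function(w) {
    sigma <- stats::mad(w)
    if (sigma == 0) return(w)
    lam <- sigma * sqrt(2 * log(length(w)))
    sign(w) * pmax(abs(w) - lam, 0)
  })
  wp_reconstruct(nodes, depth)[seq_len(n0)]
}
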