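# Dynamic time warping between multivariate feature sequences, with a
# Sakoe-Chiba band and the symmetric step pattern (diagonal weight 2).
# Normalized cost = accumulated cost / (n + m), the standard normalization
# for this step pattern.

#' Dynamic time warping distance between feature sequences
#'
#' Aligns two sequences of feature vectors (rows = time frames) with the
#' symmetric2 step pattern under a Sakoe-Chiba band and returns the
#' length-normalized alignment cost. Local distance is Euclidean between
#' frame vectors.
#'
#' @param x,y Numeric matrices (frames x features) with equal feature
#'   dimension; plain vectors are treated as single-feature sequences.
#' @param band_frac Half-width of the Sakoe-Chiba band as a fraction of the
#'   longer sequence (default 0.25); widened automatically to the minimum
#'   feasible width when the lengths differ.
#' @return Normalized DTW cost (accumulated cost / (n + m)); 0 for identical
#'   sequences.
#' @export
dtw_distance <- function(x, y, band_frac = 0.25) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  stop_if(ncol(x) != ncol(y), "feature dimensions differ")
  n <- nrow(x); m <- nrow(y)
  stop_if(n < 1 || m < 1, "empty sequence")

  # local cost matrix (Euclidean), computed via the expansion of ||a-b||^2
  xs <- rowSums(x^2); ys <- rowSums(y^2)
  d2 <- outer(xs, ys, `+`) - 2 * x %*% t(y)
  d <- sqrt(pmax(d2, 0))

  band <- max(ceiling(band_frac * max(n, m)), abs(n - m) + 1L)
  big <- .Machine$double.xmax / 4
  D <- matrix(big, n, m)
  for (i in seq_len(n)) {
    jc <- round(i * m / n)
    jlo <- max(1L, jc - band); jhi <- min(m, jc + band)
    for (j in jlo:jhi) {
      dij <- d[i, j]
      if (i == 1 && j == 1) {
        D[1, 1] <- 2 * dij
      } else {
        up <- if (i > 1) D[i - 1, j] + dij else big
        left <- if (j > 1) D[i, j - 1] + dij else big
        diag <- if (i > 1 && j > 1) D[i - 1, j - 1] + 2 * dij else big
        D[i, j] <- min(up, left, diag)
      }
    }
  }
  stop_if(D[n, m] >= big, "no feasible warping path inside the band")
  D[n, m] / (n + m)
}

# z-score a feature matrix per column (constant columns left at 0)
zscore_frames <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2, mu), 2, sdv, `/`)
}
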