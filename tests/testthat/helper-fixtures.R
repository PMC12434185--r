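# Shared fixtures and independent oracles for the test suite.

# simulate + run the full per-recording pipeline
run_pipeline <- function(profile = hemodynamic_profile(),
                         noise = noise_spec(), duration_ms = 12000) {
  sim <- generate_recording(profile, noise, duration_ms = duration_ms)
  res <- process_recording(sim$recording)
  list(sim = sim, res = res)
}

# match detected beats to ground-truth beats by nearest QRS onset
match_beats <- function(beats, truth) {
  vapply(truth$qrs_onset_ms,
         function(o) which.min(abs(beats$qrs_onset_ms - o)), integer(1))
}

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}

# exhaustive two-sided Fisher oracle (point-probability definition):
# enumerate every table with the observed margins
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force pairwise AUC oracle: P(pos > neg) + 0.5 P(tie)
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# full (unbanded) DTW oracle, plain dynamic program, symmetric2 steps
dtw_full_oracle <- function(x, y) {
  n <- nrow(x); m <- nrow(y)
  d <- as.matrix(dist(rbind(x, y)))[seq_len(n), n + seq_len(m), drop = FALSE]
  D <- matrix(Inf, n, m)
  D[1, 1] <- 2 * d[1, 1]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (i == 1 && j == 1) next
      up <- if (i > 1) D[i - 1, j] + d[i, j] else Inf
      left <- if (j > 1) D[i, j - 1] + d[i, j] else Inf
      diag <- if (i > 1 && j > 1) D[i - 1, j - 1] + 2 * d[i, j] else Inf
      D[i, j] <- min(up, left, diag)
    }
  }
  D[n, m] / (n + m)
}
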