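# Shared fixtures and independent oracles.

# A tiny unlabelled event table built by hand.
tiny_events <- function() {
  event_table(data.frame(
    fsc = c(150, 300, 50), ssc = c(100, 400, 10),
    fl1_ige = c(2, 100, 1), fl2_cd117 = c(3, 120, 1),
    fl3_7aad = c(4, 5, 2)
  ))
}

# One-population profile: everything is a lymphocyte.
single_pop_profile <- function(matrix = "LN") {
  matrix_profile(matrix, list(
    population_spec("lymphocyte", 1,
                    location = log(c(200, 80, 3, 3, 4)),
                    spread = c(0.15, 0.2, 0.4, 0.4, 0.4))
  ), background_dp_rate = 0)
}

# Independent brute-force re-implementation of the Passing-Bablok
# shifted-median and rank rules (kept deliberately separate from the
# package's vectorised code path).
pb_oracle <- function(x, y, gamma = 0.95) {
  n <- length(x)
  s <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] != x[j]) {
        sl <- (y[j] - y[i]) / (x[j] - x[i])
        if (sl != -1) s <- c(s, sl)
      }
    }
  }
  s <- sort(s)
  N <- length(s)
  K <- sum(s < -1)
  b <- if (N %% 2 == 1) s[(N + 1) / 2 + K]
  else (s[N / 2 + K] + s[N / 2 + 1 + K]) / 2
  C <- qnorm((1 + gamma) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  list(slopes = s, K = K, slope = b,
       slope_lo = if (M1 + K >= 1) s[M1 + K] else NA_real_,
       slope_hi = if (M2 + K <= N) s[M2 + K] else NA_real_,
       intercept = median(y - b * x))
}
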