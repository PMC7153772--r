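# Brute-force oracles and small signal builders shared across test files.
# The oracles deliberately re-derive every quantity from first principles
# (double loops, direct counting) so they stay independent of the package's
# compiled implementations.

# O(n^2) sample-entropy pair counting, Chebyshev distance, self-matches
# excluded: returns -log(A/B).
sampen_brute <- function(x, m = 2L, r_factor = 0.1) {
  r <- r_factor * sd(x)
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) < r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 1L
      }
    }
  }
  -log(A / B)
}

# Direct double-loop correlation sum: 2 * #{i<j: |x_i - x_j| <= t} / n^2.
corr_sum_brute <- function(x, t) {
  n <- length(x)
  vapply(t, function(tt) {
    cnt <- 0L
    for (i in seq_len(n - 1L)) {
      cnt <- cnt + sum(abs(x[(i + 1L):n] - x[i]) <= tt)
    }
    2 * cnt / n^2
  }, numeric(1))
}

make_sine <- function(freq, fs = 20, seconds = 100, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq(0, seconds, by = 1 / fs) + phase)
}

logistic_map <- function(n, x0 = 0.4) {
  x <- numeric(n); x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

# Slope-2 tent map with a tiny jitter: the exact map collapses to 0 in
# binary floating point (one bit of state is lost per iteration).
tent_map <- function(n, x0 = 0.6123, eps = 1e-10) {
  x <- numeric(n); x[1] <- x0
  for (i in 2:n) {
    v <- if (x[i - 1] < 0.5) 2 * x[i - 1] else 2 - 2 * x[i - 1]
    x[i] <- min(max(v + runif(1, -eps, eps), 1e-12), 1 - 1e-12)
  }
  x
}

# A valid 3-channel record with deterministic content for I/O tests.
make_test_record <- function(n = 1200, fs = 20, rec_wk = 24.5, del_wk = 39,
                             id = "test01", band = NULL) {
  tt <- seq_len(n) / fs
  sig <- cbind(ch1 = sin(2 * pi * 0.2 * tt),
               ch2 = cos(2 * pi * 0.3 * tt) * 2,
               ch3 = sin(2 * pi * 0.25 * tt) + 0.5 * cos(2 * pi * 0.11 * tt))
  ehg_record(id, sig, fs, rec_wk, del_wk, prefiltered_band = band)
}

# Small labeled dataset with a class shift on chosen columns.
make_feature_dataset <- function(n_min = 10, n_maj = 30, p = 5,
                                 shift_cols = 1L, shift = 2,
                                 groups = c("PE", "TE"), seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n_min + n_maj) * p), n_min + n_maj, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  X[seq_len(n_min), shift_cols] <- X[seq_len(n_min), shift_cols] + shift
  labeled_dataset(X, c(rep(groups[1], n_min), rep(groups[2], n_maj)))
}
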