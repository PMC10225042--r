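# Independent brute-force oracles used to validate the package's
# implementations. Deliberately naive: plain loops and exhaustive
# enumeration, no shared code with the package internals.

# O(n^2) sample entropy by direct template counting (Chebyshev distance,
# self-matches excluded, first n - m template starts for both lengths).
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  a_cnt <- 0
  b_cnt <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      db <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (db <= r) {
        b_cnt <- b_cnt + 1
        da <- max(abs(x[i:(i + m)] - x[j:(j + m)]))
        if (da <= r) a_cnt <- a_cnt + 1
      }
    }
  }
  if (a_cnt == 0 || b_cnt == 0) return(NA_real_)
  -log(a_cnt / b_cnt)
}

# Exhaustive two-sided signed-rank p-value over all 2^n sign assignments.
wilcoxon_enumeration_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lower <- mean(w_all <= w_obs)
  upper <- mean(w_all >= w_obs)
  min(1, 2 * min(lower, upper))
}

# Exhaustive two-sided Mann-Whitney p-value over all C(n1+n2, n1) labelings.
mann_whitney_enumeration_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  u_stat <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  combs <- utils::combn(N, n1)
  u_all <- apply(combs, 2, u_stat)
  lower <- mean(u_all <= u_obs)
  upper <- mean(u_all >= u_obs)
  min(1, 2 * min(lower, upper))
}

# Direct per-frame dB table for non-overlapping frames (trimming oracle).
frame_db_table <- function(x, flen) {
  starts <- seq(1, length(x), by = flen)
  msq <- sapply(starts, function(s) mean(x[s:min(s + flen - 1, length(x))]^2))
  10 * log10(msq / max(msq))
}

# Slow DCT-II (orthonormal) straight from the definition.
dct2_definition <- function(x) {
  n <- length(x)
  sapply(0:(n - 1), function(k) {
    a <- if (k == 0) sqrt(1 / n) else sqrt(2 / n)
    a * sum(x * cos(pi * (0:(n - 1) + 0.5) * k / n))
  })
}

make_tone <- function(freq, dur_s = 1, rate = 44100, amp = 1) {
  waveform(amp * sin(2 * pi * freq * (0:(round(dur_s * rate) - 1)) / rate),
           rate)
}
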