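# Independent oracles.  These deliberately avoid the package's
# convolution path (recursive filtering): the direct O(N^2) sum is the
# definition the implementation must reproduce.

# Direct discrete causal convolution of a multi-exponential decay with a
# unit-area IRF: M[k] = sum_{j<=k} irf[j] * sum_i alpha_i exp(-(k-j) dt / tau_i)
conv_direct_oracle <- function(irf_counts, dt, lifetimes, alphas,
                               background = 0, shift = 0) {
  n <- length(irf_counts)
  if (shift != 0) {
    k <- floor(shift); f <- shift - k
    lag_by <- function(y, m) {
      if (m >= n || m <= -n) return(numeric(n))
      if (m >= 0) c(numeric(m), y[seq_len(n - m)]) else c(y[(1 - m):n], numeric(-m))
    }
    irf_counts <- (1 - f) * lag_by(irf_counts, k) + f * lag_by(irf_counts, k + 1)
  }
  decay <- rep(0, n)
  t_rel <- (seq_len(n) - 1) * dt
  for (i in seq_along(lifetimes))
    decay <- decay + alphas[i] * exp(-t_rel / lifetimes[i])
  out <- numeric(n)
  for (k in seq_len(n))
    out[k] <- sum(irf_counts[seq_len(k)] * decay[k:1])
  out + background
}

# FWHM of a discretised histogram, by linear interpolation of the
# half-maximum crossings on either side of the peak.
measure_fwhm <- function(times, counts) {
  pk <- which.max(counts)
  half <- counts[pk] / 2
  cross <- function(idx_range, rising) {
    for (k in idx_range) {
      a <- counts[k]; b <- counts[k + 1]
      if ((rising && a < half && b >= half) ||
          (!rising && a >= half && b < half)) {
        frac <- (half - a) / (b - a)
        return(times[k] + frac * (times[k + 1] - times[k]))
      }
    }
    NA_real_
  }
  left <- cross(seq_len(pk - 1), rising = TRUE)
  right <- cross(pk:(length(counts) - 1), rising = FALSE)
  right - left
}

# Closed-form Wald-Wolfowitz two-sided p for a given sign sequence.
runs_p_oracle <- function(signs) {
  n1 <- sum(signs); n2 <- sum(!signs); n <- n1 + n2
  r <- 1 + sum(signs[-1] != signs[-n])
  mu <- 1 + 2 * n1 * n2 / n
  s2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  2 * stats::pnorm(-abs((r - mu) / sqrt(s2)))
}
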