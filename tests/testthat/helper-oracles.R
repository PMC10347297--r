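# Independent oracles used across test files. These deliberately use the
# slow, direct definitions so they stay independent of the package's
# FFT/running-sum/greedy implementations.

# Zero-normalized cross-correlation by direct evaluation per alignment.
brute_ncc <- function(x, w) {
  m <- length(w)
  wc <- w - mean(w)
  vapply(seq_len(length(x) - m + 1), function(i) {
    win <- x[i:(i + m - 1)]
    a <- win - mean(win)
    den <- sqrt(sum(a^2) * sum(wc^2))
    if (den == 0) 0 else sum(a * wc) / den
  }, numeric(1))
}

# Topographic prominence by scanning to strictly higher ground (or the
# series edge) on each side.
brute_prominence <- function(x, p) {
  h <- x[p]
  left <- x[seq_len(p - 1)]
  stopleft <- which(left > h)
  lmin <- if (length(stopleft)) min(left[(max(stopleft) + 1):(p - 1)], h)
          else min(left, h)
  right <- x[seq(p + 1, length(x))]
  stopright <- which(right > h)
  rmin <- if (length(stopright)) min(right[seq_len(min(stopright) - 1)], h)
          else min(right, h)
  h - max(lmin, rmin)
}

# Full peak-picking oracle: strict local maxima, prominence filter, greedy
# retention by descending height (earlier index on ties) with a minimum
# index spacing.
brute_pick_peaks <- function(x, min_prom, min_dist_samples) {
  n <- length(x)
  idx <- which(vapply(seq_len(n), function(i)
    i > 1 && i < n && x[i] > x[i - 1] && x[i] > x[i + 1], logical(1)))
  idx <- idx[vapply(idx, function(p) brute_prominence(x, p), numeric(1)) >=
               min_prom]
  if (!length(idx)) return(integer(0))
  ord <- idx[order(-x[idx], idx)]
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(p - kept) >= min_dist_samples - 1e-9))
      kept <- c(kept, p)
  sort(kept)
}

# Closed-form simple OLS via the normal equations.
ols_oracle <- function(xr, yr) {
  sxx <- sum((xr - mean(xr))^2)
  sxy <- sum((xr - mean(xr)) * (yr - mean(yr)))
  slope <- sxy / sxx
  intercept <- mean(yr) - slope * mean(xr)
  r2 <- sxy^2 / (sxx * sum((yr - mean(yr))^2))
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Textbook Pearson r and its two-sided t-test p-value.
pearson_oracle <- function(xr, yr) {
  r <- sum(scale(xr, scale = FALSE) * scale(yr, scale = FALSE)) /
    sqrt(sum(scale(xr, scale = FALSE)^2) * sum(scale(yr, scale = FALSE)^2))
  n <- length(xr)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}

# Amplitude of a sinusoid of known frequency in a signal (least squares
# projection onto the quadrature pair), robust to residual noise.
sine_amplitude <- function(y, fs, f_hz) {
  t <- (seq_along(y) - 1) / fs
  c1 <- 2 * mean(y * sin(2 * pi * f_hz * t))
  c2 <- 2 * mean(y * cos(2 * pi * f_hz * t))
  sqrt(c1^2 + c2^2)
}

# Lag (in samples) of the peak cross-correlation between two signals.
xcorr_peak_lag <- function(x, y, max_lag = 50) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    if (L >= 0) sum(x[seq_len(length(x) - L)] * y[(1 + L):length(y)])
    else sum(x[(1 - L):length(x)] * y[seq_len(length(y) + L)])
  }, numeric(1))
  lags[which.max(cc)]
}
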