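# Shared fixtures and brute-force oracles.

# The three rainfall stations (Nan province, August 2018-2019), entered from
# their published summary statistics.
rainfall_summaries <- function() {
  list(dln_summary(62, delta_hat = 0.7258, sigma2_hat = 1.7857,
                   mu_hat = 2.1189, group = "ChiangKlang"),
       dln_summary(62, delta_hat = 0.7903, sigma2_hat = 3.4406,
                   mu_hat = 1.6448, group = "ThaWangPha"),
       dln_summary(62, delta_hat = 0.7419, sigma2_hat = 1.8346,
                   mu_hat = 1.8971, group = "Pua"))
}

# Linear-interpolation quantile computed from first principles (sorted order
# statistics, h = (n-1)p + 1), independent of stats::quantile.
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# O(K^2)-spirited shortest-window HPD: enumerate every contiguous window of
# the sorted draws holding ceiling(level*K) points.
hpd_oracle <- function(x, level) {
  s <- sort(x)
  k <- length(s)
  m <- ceiling(level * k)
  best <- c(-Inf, Inf)
  for (i in 1:(k - m + 1L)) {
    if (s[i + m - 1L] - s[i] < best[2L] - best[1L])
      best <- c(s[i], s[i + m - 1L])
  }
  best
}
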