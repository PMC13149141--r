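# Independent brute-force oracles, deliberately written in plain R with no
# shared code paths with the package internals.

# Sample entropy by direct template enumeration.
brute_sampen <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

# Faster brute-force variant (row-vectorized) for long series; still an
# independent formulation (template loops over explicit rank comparisons).
brute_sampen_fast <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    js <- (i + 1):nt
    d <- abs(x[js] - x[i])
    for (k in 1:(m - 1)) d <- pmax(d, abs(x[js + k] - x[i + k]))
    hit <- d <= r
    B <- B + sum(hit)
    A <- A + sum(hit & abs(x[js + m] - x[i + m]) <= r)
  }
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

# One-way ANOVA F from explicit sums of squares.
oracle_anova_F <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(y) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Spearman rho from average ranks via the Pearson formula on ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Power of a tone in a series, by periodogram bin closest to f0.
tone_power <- function(x, fs, f0) {
  n <- length(x)
  X <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- (0:(n - 1)) * fs / n
  half <- f <= fs / 2
  X <- X[half]; f <- f[half]
  sum(X[abs(f - f0) < 0.5 / (n / fs) * 2])
}
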