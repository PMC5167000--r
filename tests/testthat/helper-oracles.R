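# Independent brute-force oracles, coded from textbook definitions only.
# These deliberately avoid the code paths (and base helpers) the package
# uses, so agreement is a genuine cross-check.

# OLS via the normal equations, solved as a 2x2 linear system.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

# Welch two-sample t: statistic, Satterthwaite df, two-sided p, CI.
welch_oracle <- function(x, y, conf_level = 0.95) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  crit <- qt(1 - (1 - conf_level) / 2, df)
  list(difference = mean(x) - mean(y),
       p_value = 2 * pt(-abs(tstat), df),
       ci_low = mean(x) - mean(y) - crit * sqrt(se2),
       ci_high = mean(x) - mean(y) + crit * sqrt(se2))
}

# Paired t as a one-sample t on the differences.
paired_oracle <- function(l, r) {
  d <- l - r
  n <- length(d)
  tstat <- mean(d) / sqrt(sum((d - mean(d))^2) / (n - 1) / n)
  2 * pt(-abs(tstat), n - 1)
}

# Pearson product-moment r and its t-based two-sided p.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- x - mean(x); sy <- y - mean(y)
  r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * pt(-abs(tstat), n - 2))
}

# Benjamini-Hochberg step-up from the definition: adjusted value for the
# k-th smallest p is min over j >= k of min(1, m * p_(j) / j).
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (k in seq_len(m)) {
    vals <- vapply(k:m, function(j) min(1, m * p[ord[j]] / j), 0)
    adj_sorted[k] <- min(vals)
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}
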