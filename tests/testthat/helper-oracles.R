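# Independent oracles used to cross-check the package's numerics.

# Simple linear regression by explicit normal equations, with the adjusted
# R-squared formula for 2-parameter models and the slope t-test p value.
ols_oracle <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- sxy^2 / (sxx * syy)
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  resid <- y - intercept - slope * x
  se_slope <- sqrt(sum(resid^2) / (n - 2) / sxx)
  tstat <- slope / se_slope
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r2 = r2, adj_rsq = adj,
       p_value = p)
}

# Exhaustive 1-D k-means: enumerate every contiguous partition of the sorted
# values and return the minimal total within-cluster sum of squares.
kmeans_brute <- function(x, k) {
  s <- sort(x)
  n <- length(s)
  wss <- function(v) sum((v - mean(v))^2)
  best <- Inf
  # choose k-1 split points among the n-1 gaps
  splits <- utils::combn(n - 1, k - 1, simplify = FALSE)
  for (sp in splits) {
    bounds <- c(0, sp, n)
    tot <- 0
    for (q in seq_len(k)) {
      tot <- tot + wss(s[(bounds[q] + 1):bounds[q + 1]])
    }
    if (tot < best) best <- tot
  }
  best
}

# Silhouette from the defining formula, Euclidean distance on scalars.
silhouette_oracle <- function(x, labels) {
  n <- length(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) {
      s[i] <- 0
      next
    }
    a <- mean(abs(x[i] - x[own & seq_len(n) != i]))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(abs(x[i] - x[labels == l]))
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# One-series profile table from a log10 vector, for terse test setup.
norm_profile <- function(log_values, name = "p", kind = "cytokine",
                         time = seq_along(log_values) - 1) {
  tibble::tibble(name = name, kind = kind, time = time,
                 log_value = log_values)
}

ratio_profile <- function(values, name = "p", kind = "cytokine",
                          time = seq_along(values) - 1) {
  tibble::tibble(name = name, kind = kind, time = time, value = values)
}

example_panel <- function() granulink::example_profiles()
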