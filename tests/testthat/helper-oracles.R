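# Independent brute-force oracles used across the suite.

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n1+n2, n1) rank assignments (tie-free data only). Independent of
# the package's implementation: builds the full null distribution of U.
enumerate_mw_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(!anyDuplicated(c(x, y)))
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_null <- apply(combos, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  p_low <- mean(u_null <= u_obs)
  p_high <- mean(u_null >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Global-test Q computed element by element, no matrix algebra.
brute_force_q <- function(X, y) {
  X <- as.matrix(X)
  mu <- mean(y)
  r <- y - mu
  n <- nrow(X)
  m <- ncol(X)
  total <- 0
  for (j in seq_len(m)) {
    s <- 0
    for (i in seq_len(n)) s <- s + X[i, j] * r[i]
    total <- total + s * s
  }
  total / (m * mu * (1 - mu))
}
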