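# Independent brute-force oracles and small fixture builders used across
# the test files. The oracles deliberately avoid the package's own code
# paths.

# two-pass sample variance, written out longhand
bf_variance <- function(x, denom_n = FALSE) {
  m <- sum(x) / length(x)
  dev2 <- 0
  for (xi in x) dev2 <- dev2 + (xi - m)^2
  dev2 / (length(x) - if (denom_n) 0 else 1)
}

# mean pairwise difference over all haplotype pairs, by direct enumeration
bf_pi <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(mat[i, ] != mat[j, ])
  }
  tot / (n * (n - 1) / 2)
}

# Tajima's D from first principles (textbook constants)
bf_tajima_d <- function(mat) {
  n <- nrow(mat)
  cnt <- colSums(mat)
  seg <- cnt > 0 & cnt < n
  S <- sum(seg)
  ii <- seq_len(n - 1)
  a1 <- sum(1 / ii); a2 <- sum(1 / ii^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (bf_pi(mat[, seg, drop = FALSE]) - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# unfolded theta_H by direct spectrum summation
bf_theta_h <- function(mat) {
  n <- nrow(mat)
  cnt <- colSums(mat)
  cnt <- cnt[cnt > 0 & cnt < n]
  sum(2 * cnt^2) / (n * (n - 1))
}

# a tiny deterministic window from an explicit matrix
toy_window <- function(mat, evaluated = NA_integer_) {
  haplotype_window(mat, evaluated_index = evaluated,
                   require_segregating = FALSE)
}

# random segregating 0/1 matrix (every column polymorphic)
random_window <- function(n, S, seed) {
  set.seed(seed)
  mat <- matrix(0L, n, S)
  for (j in seq_len(S)) {
    k <- sample(1:(n - 1), 1)
    mat[sample(n, k), j] <- 1L
  }
  toy_window(mat)
}
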