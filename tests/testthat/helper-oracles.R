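# Independent oracles used across the test suite.  These deliberately avoid
# the package's own evaluation paths (term-by-term loops, plain power sums,
# nested-loop counting) so they can certify the implementation.

# Mueller-Brown energy via an explicit loop over the four terms.
oracle_mb_energy <- function(q, p = NULL) {
  if (is.null(p)) {
    A <- c(-20, -10, -17, 1.5)
    a <- c(-1, -1, -6.5, 0.7)
    b <- c(0, 0, 11, 0.6)
    cc <- c(-10, -10, -6.5, 0.7)
    x0 <- c(1, 0, -0.5, -1)
    y0 <- c(0, 0.5, 1.5, 1)
  } else {
    A <- p$A; a <- p$a; b <- p$b; cc <- p$c; x0 <- p$x0; y0 <- p$y0
  }
  e <- 0
  for (n in 1:4) {
    dx <- q[1] - x0[n]
    dy <- q[2] - y0[n]
    e <- e + A[n] * exp(a[n] * dx^2 + b[n] * dx * dy + cc[n] * dy^2)
  }
  e
}

# Polynomial bias as a plain power sum (no Horner).
oracle_poly_bias <- function(x, k, coef) {
  k * sum(coef * x^seq_along(coef))
}

# Direct transition counting by a nested loop over start frames.
oracle_count_matrix <- function(dtraj, lag, n_states, weights = NULL) {
  C <- matrix(0, n_states, n_states)
  starts <- seq_len(length(dtraj) - lag)
  if (is.null(weights)) weights <- rep(1, length(starts))
  for (m in starts) {
    C[dtraj[m], dtraj[m + lag]] <- C[dtraj[m], dtraj[m + lag]] + weights[m]
  }
  C
}

# Strip everything but the dimensions (for bit-for-bit matrix comparisons).
strip_attrs <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# Standard error from non-overlapping block means.
block_se <- function(x, n_blocks = 50) {
  n <- length(x)
  bs <- floor(n / n_blocks)
  means <- vapply(seq_len(n_blocks), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  stats::sd(means) / sqrt(n_blocks)
}

weighted_block_estimates <- function(w, x, n_blocks = 50) {
  n <- length(x)
  bs <- floor(n / n_blocks)
  vapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1) * bs + 1):(b * bs)
    sum(w[idx] * x[idx]) / sum(w[idx])
  }, 0)
}
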