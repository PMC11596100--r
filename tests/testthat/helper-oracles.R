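# Independent brute-force oracles used to validate the package's
# implementations on small inputs.

# Tie-corrected Friedman statistic computed from first principles: mid-ranks
# by pairwise comparison counts, the centered form of the statistic, and the
# tie term accumulated by enumerating tied groups per block.
friedman_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  ranks <- matrix(0, n, k)
  for (i in seq_len(n)) for (j in seq_len(k)) {
    less <- sum(m[i, ] < m[i, j])
    equal <- sum(m[i, ] == m[i, j])  # includes self
    ranks[i, j] <- less + (equal + 1) / 2
  }
  Rj <- colSums(ranks)
  chi_u <- 12 * sum((Rj - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  tie_term <- 0
  for (i in seq_len(n)) {
    for (v in unique(m[i, ])) {
      t <- sum(m[i, ] == v)
      tie_term <- tie_term + t^3 - t
    }
  }
  C <- 1 - tie_term / (n * k * (k^2 - 1))
  if (C <= 0) return(list(chi = 0, C = 0, Rj = Rj, degenerate = TRUE))
  list(chi = chi_u / C, C = C, Rj = Rj, degenerate = FALSE)
}

# Direct 2-d convolution with a normalized Gaussian kernel and replicated
# edges, matching the smoothing configuration of the processing pipeline.
gaussian_conv_oracle <- function(m, sigma) {
  radius <- 2 * ceiling(3 * sigma) + 1
  half <- (radius - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- min(max(i + di, 1), h)
      jj <- min(max(j + dj, 1), w)
      acc <- acc + kern[di + half + 1, dj + half + 1] * m[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# small deterministic test frame of integer gray levels
make_gradient_frame <- function(h = 32, w = 32) {
  outer(seq_len(h) - 1, seq_len(w) - 1,
        function(i, j) (i * 7 + j * 3) %% 256)
}
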