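# Independent brute-force oracles, deliberately coded without reusing the
# package's (or stats') implementation paths.

# Spearman rho: Pearson correlation of mid-ranks, computed from first
# principles (sums, no stats::cor).
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Benjamini-Hochberg step-up, written as the literal procedure on sorted
# p-values with a cumulative minimum from the largest rank down.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Rank position oracle: (position in ascending sort)/(N+1), ties by first
# occurrence of the value's sorted position.
oracle_sort_rank <- function(x) {
  s <- sort(x)
  unname(vapply(x, function(xi) match(xi, s), numeric(1))) / (length(x) + 1)
}

# Triple-loop matrix product.
oracle_matmul <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(B)))
      for (l in seq_len(ncol(A)))
        out[i, j] <- out[i, j] + A[i, l] * B[l, j]
  out
}

# Median-quotient normalizer oracle for PQN.
oracle_pqn_factors <- function(mat) {
  ref <- apply(mat, 2, median)
  apply(mat, 1, function(r) median(r / ref))
}

# Small labelled matrix builder for terse test setup.
toy_matrix <- function(data, nrow, byrow = TRUE, samples = NULL, features = NULL) {
  m <- matrix(data, nrow = nrow, byrow = byrow)
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- features %||% paste0("f", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
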