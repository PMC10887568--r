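# Independent brute-force oracles, deliberately written as direct
# transcriptions of the definitions (no hashing, no early exit, no shared
# code with the package kernels).

# Chebyshev distance between the size-m templates at two 1-based anchors.
oracle_template_dist <- function(u, k1, l1, k2, l2, m) {
  X <- u[k1:(k1 + m - 1), l1:(l1 + m - 1), drop = FALSE]
  Y <- u[k2:(k2 + m - 1), l2:(l2 + m - 1), drop = FALSE]
  max(abs(X - Y))
}

# Naive double loop over unordered pairs of the supplied anchors.
oracle_count_pairs <- function(u, coords, m, r) {
  n <- nrow(coords)
  if (n < 2) return(0)
  cnt <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (coords[i, 1] == coords[j, 1] && coords[i, 2] == coords[j, 2]) next
      d <- oracle_template_dist(u, coords[i, 1], coords[i, 2],
                                coords[j, 1], coords[j, 2], m)
      if (d <= r) cnt <- cnt + 1
    }
  }
  cnt
}

# All anchors of the shared restricted range (margin = base m).
oracle_anchors <- function(h, w, margin) {
  as.matrix(expand.grid(k = seq_len(h - margin), l = seq_len(w - margin)))
}

# Naive exact SampEn2D pieces over the shared anchor set.
oracle_exact_counts <- function(u, m, r) {
  anc <- oracle_anchors(nrow(u), ncol(u), m)
  c(A = oracle_count_pairs(u, anc, m, r),
    B = oracle_count_pairs(u, anc, m + 1, r))
}

oracle_sampen2d <- function(u, m, r) {
  ab <- oracle_exact_counts(u, m, r)
  -log(ab["B"] / ab["A"])[[1]]
}

# Per-anchor match fractions phi^m(r) (own anchor range, denominator
# (h-m)(w-m) - 1 per anchor), enumerated one anchor at a time.
oracle_phi <- function(u, m, r) {
  anc <- oracle_anchors(nrow(u), ncol(u), m)
  n <- nrow(anc)
  fr <- vapply(seq_len(n), function(i) {
    d <- vapply(seq_len(n), function(j) {
      if (i == j) return(Inf)
      oracle_template_dist(u, anc[i, 1], anc[i, 2], anc[j, 1], anc[j, 2], m)
    }, numeric(1))
    sum(d <= r) / (n - 1)
  }, numeric(1))
  mean(fr)
}

# Faster enumeration oracle for mid-sized images: still evaluates every
# pairwise Chebyshev distance directly, but vectorized one anchor at a
# time over the flattened template matrix (no counting shortcuts).
oracle_exact_counts_vec <- function(u, m, r) {
  count_for_size <- function(s) {
    anc <- oracle_anchors(nrow(u), ncol(u), m)  # shared margin m
    n <- nrow(anc)
    tm <- matrix(NA_real_, n, s * s)
    for (i in seq_len(n)) {
      tm[i, ] <- as.vector(u[anc[i, 1]:(anc[i, 1] + s - 1),
                             anc[i, 2]:(anc[i, 2] + s - 1)])
    }
    cnt <- 0
    for (i in seq_len(n - 1)) {
      rest <- (i + 1):n
      d <- abs(tm[rest, 1] - tm[i, 1])
      for (s2 in 2:(s * s)) d <- pmax(d, abs(tm[rest, s2] - tm[i, s2]))
      cnt <- cnt + sum(d <= r)
    }
    cnt
  }
  c(A = count_for_size(m), B = count_for_size(m + 1))
}

oracle_sampen2d_vec <- function(u, m, r) {
  ab <- oracle_exact_counts_vec(u, m, r)
  -log(ab[["B"]] / ab[["A"]])
}
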