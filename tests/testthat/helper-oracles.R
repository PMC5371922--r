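# Independent oracles, kept free of the package's own DTW/ROC code paths.

# Exhaustive enumeration of all monotone warping paths (steps (1,0), (0,1),
# (1,1)) from (1,1) to (m,n); returns the minimal accumulated |a_i - b_j|
# cost. Exponential, for tiny series only.
dtw_brute_force <- function(a, b) {
  m <- length(a); n <- length(b)
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == m && j == n) return(c0)
    best <- Inf
    if (i < m) best <- min(best, rec(i + 1, j))
    if (j < n) best <- min(best, rec(i, j + 1))
    if (i < m && j < n) best <- min(best, rec(i + 1, j + 1))
    c0 + best
  }
  rec(1, 1)
}

# Pairwise concordance probability with half-credit for ties: the
# probability a random positive scores above a random negative.
auc_concordance <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == -1]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Exact minimal DTW cover: smallest number of representatives such that
# every cycle is within `threshold` of (or is) a representative, by
# exhaustive subset search on the given distance matrix.
minimal_cover_size <- function(D, threshold) {
  n <- nrow(D)
  for (size in 1:n) {
    for (combo in utils::combn(n, size, simplify = FALSE)) {
      covered <- apply(D[combo, , drop = FALSE] < threshold, 2, any) |
        seq_len(n) %in% combo
      if (all(covered)) return(size)
    }
  }
  n
}

# Mean squared amplitude inside the ground-truth systolic windows.
systolic_energy <- function(recording, truth, trim_s = 0.04) {
  fs <- recording$sample_rate_hz
  vals <- numeric(0)
  for (k in seq_along(truth$s2_times_s)) {
    a <- floor((truth$s1_times_s[k] + trim_s) * fs) + 1
    b <- floor((truth$s2_times_s[k] - trim_s) * fs)
    if (b > a) vals <- c(vals, recording$samples[a:b]^2)
  }
  mean(vals)
}
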