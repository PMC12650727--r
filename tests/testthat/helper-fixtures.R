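# Shared fixtures and independent oracles. Oracles are deliberately naive
# (explicit loops, textbook formulas) and never call the code paths they
# check.

# Single-edge (2-node) dynamic network with the given weight series.
one_edge_net <- function(series) {
  dynamic_network(lapply(series, function(w) matrix(c(0, w, w, 0), 2, 2)))
}

# Random valid dynamic network.
random_net <- function(n = 4L, tt = 3L) {
  mats <- lapply(seq_len(tt), function(t) {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, -1, 2)
    m + t(m)
  })
  dynamic_network(mats)
}

# Oracle: population sd.
naive_pop_sd <- function(x) sqrt(sum((x - mean(x))^2) / length(x))

# Oracle: long vector via an explicit (t, i, j) triple loop.
naive_long_vector <- function(net) {
  out <- numeric(0)
  for (t in seq_len(dim(net$weights)[1])) {
    for (i in seq_len(dim(net$weights)[2])) {
      for (j in seq_len(dim(net$weights)[3])) {
        if (i < j) out <- c(out, net$weights[t, i, j])
      }
    }
  }
  out
}

# Oracle: DNS from first principles on the naive long vectors.
naive_dns <- function(a, b) {
  va <- naive_long_vector(a)
  vb <- naive_long_vector(b)
  r <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  (r * min(naive_pop_sd(va), naive_pop_sd(vb)) /
      max(naive_pop_sd(va), naive_pop_sd(vb)) + 1) / 2
}

# Apply one node permutation to every snapshot of a network.
permute_nodes <- function(net, perm) {
  w <- net$weights
  for (t in seq_len(dim(w)[1])) w[t, , ] <- w[t, perm, perm]
  dynamic_network(w)
}

# Apply one timepoint permutation.
permute_time <- function(net, perm) {
  dynamic_network(net$weights[perm, , , drop = FALSE])
}
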