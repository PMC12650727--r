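# DNS/DNES and the traditional comparators: hand-derived values,
# zero-variance conventions, and the algebraic properties of the indices.

test_that("pearson_corr matches hand-computed values and rejects degenerates", {
  expect_equal(pearson_corr(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_corr(c(1, 2), c(2, 1)), -1)
  expect_equal(pearson_corr(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_corr(c(1, 2), c(1, 2, 3)), "length")
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
})

test_that("dns reproduces the hand-derived single-edge values", {
  A <- one_edge_net(c(1, 2))
  expect_equal(dns(A, A)$value, 1)
  expect_equal(dns(A, one_edge_net(c(2, 4)))$value, 0.75)
  expect_equal(dns(A, one_edge_net(c(2, 1)))$value, 0)
  expect_error(dns(A, one_edge_net(c(1, 2, 3))), "not aligned")
})

test_that("dns components are reported to full precision", {
  A <- one_edge_net(c(1, 2))
  B <- one_edge_net(c(2, 4))
  comp <- dns(A, B)$components
  expect_equal(comp$corr_term, 1)
  expect_equal(comp$sd_a, 0.5)
  expect_equal(comp$sd_b, 1)
  expect_equal(comp$sd_ratio, 0.5)
})

test_that("dns zero-variance conventions", {
  flatA <- one_edge_net(c(1, 1))
  expect_equal(dns(flatA, flatA)$value, 1)                  # constant, equal
  expect_equal(dns(flatA, one_edge_net(c(2, 2)))$value, 0.5) # constant, unequal
  expect_equal(dns(flatA, one_edge_net(c(1, 2)))$value, 0.5) # one constant
})

test_that("dnes reproduces the hand-derived values", {
  A <- one_edge_net(c(1, 2, 3))
  expect_equal(dnes(A, A)$value, 1)
  expect_equal(dnes(A, one_edge_net(c(2, 4, 6)))$value, 0.75)

  # two-edge nets: edge (1,2) identical (S = 1), edge (1,3) anti-phase with
  # equal sd (S = -1), edge (2,3) constant-equal (S = 1) -> mean 1/3
  mk <- function(e12, e13) dynamic_network(lapply(seq_along(e12), function(t) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- e12[t]
    m[1, 3] <- m[3, 1] <- e13[t]
    m
  }))
  A2 <- mk(c(1, 2), c(1, 2))
  B2 <- mk(c(1, 2), c(2, 1))
  s <- dnes(A2, B2)$components$per_edge_S
  expect_equal(s, c(1, -1, 1))
  expect_equal(dnes(A2, B2)$value, (1 / 3 + 1) / 2)

  expect_error(dnes(one_edge_net(1), one_edge_net(1)), "at least 2 timepoints")
})

test_that("sd_decomposition conserves total variance (Eq.-3 split)", {
  d <- sd_decomposition(one_edge_net(c(1, 3)))
  expect_equal(d$within_term, 0)
  expect_equal(d$between_term, 1)
  expect_equal(d$total_variance, 1)

  # identical snapshots at every timepoint -> no temporal evolution
  set.seed(5)
  snap <- random_net(4, 1)$weights[1, , ]
  static <- dynamic_network(list(snap, snap, snap))
  expect_equal(sd_decomposition(static)$between_term, 0)

  # constant matrices c_t * ones -> no strength span
  ones <- matrix(1, 4, 4); diag(ones) <- 0
  flat <- dynamic_network(list(1 * ones, 3 * ones, 2 * ones))
  expect_equal(sd_decomposition(flat)$within_term, 0)

  set.seed(6)
  for (rep in 1:10) {
    net <- random_net(n = sample(3:6, 1), tt = sample(2:5, 1))
    d <- sd_decomposition(net)
    v <- as.numeric(flatten_long_vector(net))
    expect_equal(d$within_term + d$between_term,
                 naive_pop_sd(v)^2, tolerance = 1e-10)
    expect_equal(d$total_variance, naive_pop_sd(v)^2, tolerance = 1e-10)
  }
})

test_that("dns equals the naive triple-loop oracle on random instances", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(2:5, 1); tt <- sample(2:5, 1)
    a <- random_net(n, tt); b <- random_net(n, tt)
    expect_equal(dns(a, b)$value, naive_dns(a, b), tolerance = 1e-12)
  }
})

test_that("duplicating the edge universe (both triangles) leaves DNS unchanged", {
  # the full-matrix reshaping counts every off-diagonal entry twice; matched
  # duplication rescales numerator and denominator identically
  set.seed(8)
  a <- random_net(4, 3); b <- random_net(4, 3)
  dup <- function(net) {
    va <- as.numeric(flatten_long_vector(net))
    rep(va, each = 2)
  }
  va <- dup(a); vb <- dup(b)
  r <- cor(va, vb) * min(naive_pop_sd(va), naive_pop_sd(vb)) /
    max(naive_pop_sd(va), naive_pop_sd(vb))
  expect_equal((r + 1) / 2, dns(a, b)$value, tolerance = 1e-12)
})

test_that("amplitude law: DNS(A, cA) = (1 + min(c, 1/c)) / 2", {
  set.seed(9)
  net <- random_net(4, 3)
  for (c0 in c(0.2, 0.5, 1, 2, 7.5)) {
    scaled <- dynamic_network(net$weights * c0)
    expect_equal(dns(net, scaled)$value, (1 + min(c0, 1 / c0)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("dice and jaccard match set-overlap arithmetic", {
  edge_set <- function(pairs, n = 4) {
    m <- matrix(0, n, n)
    for (p in pairs) m[p[1], p[2]] <- m[p[2], p[1]] <- 1
    m
  }
  a <- edge_set(list(c(1, 2), c(1, 3)))
  b <- edge_set(list(c(1, 3), c(3, 4)))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)         # 2*1 / (2+2)
  expect_equal(jaccard(a, b), 1 / 3)    # 1 / 3
  disjoint <- edge_set(list(c(2, 4)))
  expect_equal(dice(a, disjoint), 0)
  empty <- matrix(0, 4, 4)
  expect_equal(dice(empty, empty), 1)
  expect_equal(jaccard(empty, empty), 1)
  expect_error(dice(a * 0.5, b), "not binary")
})

test_that("jaccard-dice identity holds on random binary pairs", {
  set.seed(10)
  for (rep in 1:15) {
    a <- binarize(random_net(5, 1)$weights[1, , ], 0.5)
    b <- binarize(random_net(5, 1)$weights[1, , ], 0.5)
    dsc <- dice(a, b)
    expect_equal(jaccard(a, b), dsc / (2 - dsc), tolerance = 1e-12)
  }
})

test_that("spectral similarity: closed-form and relabeling cases", {
  e1 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(spectral_similarity(e1, e1), 1)
  expect_equal(laplacian_spectrum(e1), c(0, 2))
  expect_equal(spectral_similarity(e1, matrix(0, 2, 2)), 0)
  expect_equal(spectral_similarity(matrix(0, 2, 2), matrix(0, 2, 2)), 1)

  # isomorphic graphs under node relabeling share the spectrum
  set.seed(12)
  m <- random_net(5, 1)$weights[1, , ]
  m <- abs(m)
  perm <- sample(5)
  expect_equal(spectral_similarity(m, m[perm, perm]), 1, tolerance = 1e-9)
})

test_that("normalized-Laplacian spectra lie in [0, 2]", {
  set.seed(13)
  for (rep in 1:10) {
    m <- abs(random_net(sample(3:7, 1), 1)$weights[1, , ])
    ev <- laplacian_spectrum(m)
    expect_true(all(ev >= -1e-9 & ev <= 2 + 1e-9))
  }
})

test_that("corr_norm matches hand values", {
  v <- function(vals) {
    m <- matrix(0, 4, 4)
    m[lower.tri(m)] <- 0; m <- m + t(m)
    p <- edge_pairs(4)
    for (k in seq_len(nrow(p))) m[p[k, 1], p[k, 2]] <- m[p[k, 2], p[k, 1]] <- vals[k]
    m
  }
  a <- v(c(1, 2, 3, 4, 5, 6))
  expect_equal(corr_norm(a, a), 1)
  expect_equal(corr_norm(a, v(-c(1, 2, 3, 4, 5, 6))), 0)
  b <- v(c(1, 3, 2, 4, 5, 6))  # swaps two entries: corr on 6 edges
  expect_equal(corr_norm(a, b), (1 + cor(c(1, 2, 3, 4, 5, 6),
                                         c(1, 3, 2, 4, 5, 6))) / 2)
})

test_that("traditional similarity of dynamic networks is the timepoint mean", {
  a1 <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)   # triangle
  b1 <- a1                                            # dice 1
  a2 <- a1
  b2 <- matrix(0, 3, 3); b2[1, 2] <- b2[2, 1] <- 1    # dice 2*1/(3+1) = 0.5
  A <- dynamic_network(list(a1, a2))
  B <- dynamic_network(list(b1, b2))
  res <- traditional_dynamic_similarity(A, B, "dice")
  expect_equal(res$components$per_timepoint, c(1, 0.5))
  expect_equal(res$value, 0.75)
  # T = 1 reduces to the snapshot index
  expect_equal(traditional_dynamic_similarity(dynamic_network(list(a1)),
                                              dynamic_network(list(b2)),
                                              "jaccard")$value,
               jaccard(a1, b2))
})

test_that("all six indices are symmetric, in [0,1], and 1 at identity", {
  set.seed(14)
  for (rep in 1:6) {
    a <- random_net(4, 3)
    b <- random_net(4, 3)
    ab <- binarize(a, 0.5); bb <- binarize(b, 0.5)
    vals <- c(
      dns = dns(a, b)$value, dnes = dnes(a, b)$value,
      dice = traditional_dynamic_similarity(ab, bb, "dice")$value,
      jaccard = traditional_dynamic_similarity(ab, bb, "jaccard")$value,
      spectral = traditional_dynamic_similarity(ab, bb, "spectral")$value,
      corr = traditional_dynamic_similarity(a, b, "corr")$value)
    rev_vals <- c(
      dns = dns(b, a)$value, dnes = dnes(b, a)$value,
      dice = traditional_dynamic_similarity(bb, ab, "dice")$value,
      jaccard = traditional_dynamic_similarity(bb, ab, "jaccard")$value,
      spectral = traditional_dynamic_similarity(bb, ab, "spectral")$value,
      corr = traditional_dynamic_similarity(b, a, "corr")$value)
    expect_equal(vals, rev_vals, tolerance = 1e-12)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(dns(a, a)$value, 1)
    expect_equal(dnes(a, a)$value, 1)
    expect_equal(traditional_dynamic_similarity(ab, ab, "dice")$value, 1)
    expect_equal(traditional_dynamic_similarity(a, a, "corr")$value, 1)
  }
})

test_that("dnes is invariant to a shared node relabeling", {
  set.seed(15)
  a <- random_net(5, 4); b <- random_net(5, 4)
  perm <- sample(5)
  expect_equal(dnes(permute_nodes(a, perm), permute_nodes(b, perm))$value,
               dnes(a, b)$value, tolerance = 1e-12)
})

test_that("dns and dnes are invariant to a shared timepoint permutation", {
  set.seed(16)
  a <- random_net(4, 5); b <- random_net(4, 5)
  perm <- sample(5)
  expect_equal(dns(permute_time(a, perm), permute_time(b, perm))$value,
               dns(a, b)$value, tolerance = 1e-12)
  expect_equal(dnes(permute_time(a, perm), permute_time(b, perm))$value,
               dnes(a, b)$value, tolerance = 1e-12)
})

test_that("similarity_indices dispatches and binarizes as requested", {
  set.seed(17)
  a <- random_net(4, 2); b <- random_net(4, 2)
  res <- similarity_indices(a, b, c("dns", "dice"), binarize_threshold = 0.5)
  expect_named(res, c("dns", "dice"))
  expect_equal(res$dns$value, dns(a, b)$value)
  expect_equal(res$dice$value,
               traditional_dynamic_similarity(binarize(a, 0.5),
                                              binarize(b, 0.5), "dice")$value)
})
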