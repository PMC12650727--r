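# DNS and DNES similarity indices for dynamic weighted networks, plus the
# four traditional snapshot comparators (Dice, Jaccard, normalized-Laplacian
# spectral similarity, normalized Pearson) used as baselines.

# Population standard deviation (divide by count, matching the 1/(nm)
# normalization of the long-vector variance).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Pearson product-moment correlation
#'
#' Thin wrapper around the standard estimator with the degenerate cases made
#' explicit: both inputs must have positive variance.
#'
#' @param x,y Equal-length numeric vectors, length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors differ in length: ", length(x), " vs ", length(y))
  if (length(x) < 2L) stop("correlation needs at least 2 observations")
  if (pop_sd(x) == 0 || pop_sd(y) == 0)
    stop("zero-variance input: correlation is undefined for a constant vector")
  stats::cor(x, y)
}

# Corr * min(sd)/max(sd) similarity term with the zero-variance conventions:
#   both constant and equal   -> 1   (identical degenerate signals)
#   both constant and unequal -> 0
#   exactly one constant      -> 0   (ratio -> 0 as one sd -> 0)
sim_term <- function(x, y) {
  if (identical(x, y) && pop_sd(x) > 0) return(1)  # exact self-similarity
  sx <- pop_sd(x); sy <- pop_sd(y)
  if (sx == 0 && sy == 0) return(if (isTRUE(all.equal(x, y))) 1 else 0)
  if (sx == 0 || sy == 0) return(0)
  min(max(stats::cor(x, y) * min(sx, sy) / max(sx, sy), -1), 1)
}

new_index_value <- function(name, value, components = list()) {
  structure(list(name = name, value = value, components = components),
            class = "index_value")
}

#' @export
print.index_value <- function(x, ...) {
  cat("<index_value> ", x$name, " = ", format(x$value, digits = 6), "\n",
      sep = "")
  invisible(x)
}

#' Dynamic Network Similarity (DNS)
#'
#' Similarity of two dynamic networks computed on their long vectors
#' (see [flatten_long_vector()]):
#' \deqn{DNS = \frac{1}{2}\left(Corr(V_A, V_B)\,
#'   \frac{\min(\sigma(V_A), \sigma(V_B))}{\max(\sigma(V_A), \sigma(V_B))}
#'   + 1\right)}
#' The Pearson term captures the similarity of the evolutionary trend and
#' structural topological distribution; the standard-deviation ratio corrects
#' for its amplitude blindness, capturing the evolving relative amplitude and
#' connectivity strength span. The affine map puts the index in `[0, 1]`
#' (1 = perfect correlation with matched amplitudes, 0 = perfect
#' anticorrelation with matched amplitudes).
#'
#' @param a,b Aligned `dynamic_network` objects (same `n` and `T`; node
#'   correspondence is by position).
#' @param strict_labels If `TRUE`, error when node label lists differ.
#' @return An `index_value` with `$value` in `[0, 1]` and `$components`
#'   holding `corr_term` (the Pearson correlation), `sd_a`, `sd_b`,
#'   `sd_ratio` (population SDs).
#' @details If both long vectors are constant the index is 1 when they are
#'   equal and 0.5 otherwise; if exactly one is constant the similarity term
#'   is 0 (DNS = 0.5). These conventions follow the continuity of the
#'   min/max SD ratio as one sigma tends to 0.
#' @seealso [dnes()] for the evolution-only counterpart.
#' @export
dns <- function(a, b, strict_labels = FALSE) {
  check_aligned(a, b, strict_labels)
  va <- as.numeric(flatten_long_vector(a))
  vb <- as.numeric(flatten_long_vector(b))
  sa <- pop_sd(va); sb <- pop_sd(vb)
  corr <- if (sa > 0 && sb > 0) stats::cor(va, vb) else NA_real_
  ratio <- if (max(sa, sb) > 0) min(sa, sb) / max(sa, sb) else NA_real_
  term <- sim_term(va, vb)
  new_index_value("DNS", (term + 1) / 2,
                  list(corr_term = corr, sd_a = sa, sd_b = sb,
                       sd_ratio = ratio))
}

#' Dynamic Network Evolution Similarity (DNES)
#'
#' Measures only the temporal synchronization of the two networks' dynamics.
#' For the `i`-th corresponding edge pair, with edge time series `E_A^i` and
#' `E_B^i`,
#' \deqn{S_i = Corr(E_A^i, E_B^i)\,
#'   \frac{\min(SD(E_A^i), SD(E_B^i))}{\max(SD(E_A^i), SD(E_B^i))}}
#' and \eqn{DNES = (\bar S + 1)/2}, the mean taken over all
#' `m = n(n-1)/2` edges. By construction DNES is insensitive to purely
#' structural differences (it never compares weights across different edges).
#'
#' @inheritParams dns
#' @return An `index_value` with `$value` in `[0, 1]` and
#'   `$components$per_edge_S` the vector of `S_i`.
#' @details Requires `T >= 2` (a single snapshot has no evolution to
#'   compare). With `T = 2` every per-edge correlation is +-1, so `S_i`
#'   reduces to the signed SD ratio of the two pre/post changes; this is the
#'   regime of the pre/post dynamic motor network. Constant-series
#'   conventions are as in [dns()], applied per edge.
#' @export
dnes <- function(a, b, strict_labels = FALSE) {
  check_aligned(a, b, strict_labels)
  if (n_timepoints(a) < 2L)
    stop("DNES needs at least 2 timepoints; a single snapshot has no ",
         "evolution to compare")
  ea <- edge_time_series(a)
  eb <- edge_time_series(b)
  s <- vapply(seq_len(ncol(ea)),
              function(i) sim_term(ea[, i], eb[, i]), numeric(1L))
  new_index_value("DNES", (mean(s) + 1) / 2, list(per_edge_S = s))
}

#' Long-vector variance decomposition
#'
#' The population variance of the long vector of a dynamic network splits
#' exactly into two terms when the node and edge counts are fixed over time:
#' \deqn{\sigma^2(V) = \frac{1}{Tm}\sum_{t=1}^{T}\sum_{j=1}^{m}
#'   (V_{tj} - \bar V_t)^2 + \frac{1}{T}\sum_{t=1}^{T}(\bar V_t - \bar V)^2}
#' The first (within-timepoint) term measures the connectivity strength span
#' of the individual edge strengths; the second (between-timepoint) term is
#' the variance of the mean network strength across time, i.e. the evolving
#' relative amplitude.
#'
#' @param net A `dynamic_network`.
#' @return A list with `within_term`, `between_term` and `total_variance`
#'   (`= within + between =` population variance of the long vector).
#' @export
sd_decomposition <- function(net) {
  ets <- edge_time_series(net)            # T x m
  tbar <- rowMeans(ets)                   # per-timepoint mean strength
  within <- mean((ets - tbar)^2)
  between <- mean((tbar - mean(tbar))^2)
  list(within_term = within, between_term = between,
       total_variance = within + between)
}

## ---------------------------------------------------------------------------
## Traditional snapshot comparators

check_binary_snapshot <- function(m, arg) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > SYMMETRY_TOL)
    stop("`", arg, "` must be a symmetric square matrix")
  if (!all(m %in% c(0, 1)))
    stop("`", arg, "` is not binary; binarize it first (see binarize())")
  m
}

#' Dice coefficient of two binary snapshots
#'
#' `DSC = 2|E_A intersect E_B| / (|E_A| + |E_B|)` over the off-diagonal edge
#' sets. Two empty networks are defined as identical (`DSC = 1`).
#'
#' @param a_bin,b_bin Symmetric binary (0/1) adjacency matrices of equal size.
#' @return Value in `[0, 1]`.
#' @export
dice <- function(a_bin, b_bin) {
  a <- upper_vec(check_binary_snapshot(a_bin, "a_bin"))
  b <- upper_vec(check_binary_snapshot(b_bin, "b_bin"))
  if (length(a) != length(b)) stop("snapshots differ in size")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a * b) / (na + nb)
}

#' Jaccard coefficient of two binary snapshots
#'
#' `JCD = |E_A intersect E_B| / |E_A union E_B|`; two empty networks give 1.
#' Identity with Dice: `JCD = DSC / (2 - DSC)`.
#'
#' @inheritParams dice
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(a_bin, b_bin) {
  a <- upper_vec(check_binary_snapshot(a_bin, "a_bin"))
  b <- upper_vec(check_binary_snapshot(b_bin, "b_bin"))
  if (length(a) != length(b)) stop("snapshots differ in size")
  uni <- sum(pmax(a, b))
  if (uni == 0) return(1)
  sum(a * b) / uni
}

#' Normalized-Laplacian spectrum of a snapshot
#'
#' Eigenvalues of `L = D^(-1/2) (D - M) D^(-1/2)`, where `M` is the
#' (nonnegative) adjacency matrix and `D` the diagonal degree/strength
#' matrix. Isolated nodes (zero degree) get `D^(-1/2)` entries of 0, hence
#' eigenvalue 0. The spectrum lies in `[0, 2]`.
#'
#' @param m Symmetric adjacency matrix with nonnegative weights.
#' @return Eigenvalues sorted ascending.
#' @export
laplacian_spectrum <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > SYMMETRY_TOL)
    stop("`m` must be a symmetric square matrix")
  if (min(m) < 0)
    stop("normalized Laplacian requires nonnegative weights; ",
         "binarize or rectify the snapshot first")
  d <- rowSums(m)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  l <- -m * tcrossprod(dinv)
  diag(l) <- ifelse(d > 0, 1, 0)
  sort(eigen(l, symmetric = TRUE, only.values = TRUE)$values)
}

#' Spectral similarity of two snapshots
#'
#' Compares the normalized-Laplacian spectra, sorted ascending and paired by
#' rank:
#' \deqn{SS = 1 - \frac{\sqrt{\sum_i (\lambda_i^A - \lambda_i^B)^2}}
#'   {\max\left(\sqrt{\sum_i (\lambda_i^A)^2},
#'              \sqrt{\sum_i (\lambda_i^B)^2}\right)}}
#' `SS = 1` iff the spectra are identical (in particular for isomorphic
#' graphs under node relabeling); the distance attains its maximum when one
#' spectrum is all-zero (empty graph) and the other is not. Two empty graphs
#' give `SS = 1`.
#'
#' @param a_snap,b_snap Symmetric adjacency matrices (weighted nonnegative or
#'   binary) of equal size.
#' @return Value in `[0, 1]`.
#' @export
spectral_similarity <- function(a_snap, b_snap) {
  la <- laplacian_spectrum(a_snap)
  lb <- laplacian_spectrum(b_snap)
  if (length(la) != length(lb)) stop("snapshots differ in size")
  denom <- max(sqrt(sum(la^2)), sqrt(sum(lb^2)))
  if (denom == 0) return(1)   # both empty: identical
  sd_norm <- sqrt(sum((la - lb)^2)) / denom
  min(max(1 - sd_norm, 0), 1)
}

#' Normalized Pearson similarity of two snapshots
#'
#' Pearson correlation of the vectorized snapshots (off-diagonal edge
#' vectors), affinely mapped to `[0, 1]`: `Corr_norm = (1 + Corr) / 2`.
#'
#' @param a_snap,b_snap Symmetric adjacency matrices of equal size; both must
#'   be non-constant over the edge universe.
#' @return Value in `[0, 1]`.
#' @export
corr_norm <- function(a_snap, b_snap) {
  a <- as.matrix(a_snap); b <- as.matrix(b_snap)
  if (!all(dim(a) == dim(b))) stop("snapshots differ in size")
  va <- upper_vec(a); vb <- upper_vec(b)
  (1 + pearson_corr(va, vb)) / 2
}

#' Binarize a weighted snapshot or dynamic network
#'
#' @param x A symmetric matrix or a `dynamic_network`.
#' @param threshold Edges with weight strictly greater than `threshold` are
#'   kept.
#' @return Binary object of the same shape.
#' @export
binarize <- function(x, threshold = 0) {
  if (inherits(x, "dynamic_network")) {
    w <- (x$weights > threshold) * 1
    for (t in seq_len(dim(w)[1L])) diag(w[t, , ]) <- 0
    return(dynamic_network(w, x$node_labels, x$time_labels))
  }
  m <- (as.matrix(x) > threshold) * 1
  diag(m) <- 0
  m
}

#' Traditional similarity of two dynamic networks
#'
#' The static comparators have no notion of time; following common practice
#' their per-timepoint values are averaged: the similarity of two dynamic
#' networks under a traditional index is the arithmetic mean of the snapshot
#' index over the `T` timepoints.
#'
#' @param a,b Aligned `dynamic_network` objects. For `"dice"`/`"jaccard"` the
#'   snapshots must already be binary (see [binarize()]).
#' @param index_name One of `"dice"`, `"jaccard"`, `"spectral"`, `"corr"`.
#' @return An `index_value` with `$components$per_timepoint` the `T` snapshot
#'   values.
#' @export
traditional_dynamic_similarity <- function(a, b,
    index_name = c("dice", "jaccard", "spectral", "corr")) {
  index_name <- match.arg(index_name)
  check_aligned(a, b)
  fn <- switch(index_name, dice = dice, jaccard = jaccard,
               spectral = spectral_similarity, corr = corr_norm)
  vals <- vapply(seq_len(n_timepoints(a)), function(t)
    fn(a$weights[t, , ], b$weights[t, , ]), numeric(1L))
  new_index_value(index_name, mean(vals), list(per_timepoint = vals))
}

#' Compute a set of similarity indices between two dynamic networks
#'
#' Convenience front end used by the `compare` CLI subcommand.
#'
#' @param a,b Aligned `dynamic_network` objects.
#' @param indices Character vector from
#'   `c("dns", "dnes", "dice", "jaccard", "spectral", "corr")`.
#' @param binarize_threshold If non-`NULL`, networks are binarized at this
#'   threshold before Dice/Jaccard (required when the inputs are weighted).
#' @return Named list of `index_value` objects.
#' @export
similarity_indices <- function(a, b,
    indices = c("dns", "dnes", "dice", "jaccard", "spectral", "corr"),
    binarize_threshold = NULL) {
  indices <- match.arg(indices, several.ok = TRUE)
  ab <- if (!is.null(binarize_threshold))
    list(binarize(a, binarize_threshold), binarize(b, binarize_threshold))
  else list(a, b)
  out <- lapply(indices, function(ix) {
    switch(ix,
           dns = dns(a, b),
           dnes = dnes(a, b),
           traditional_dynamic_similarity(ab[[1L]], ab[[2L]], ix))
  })
  names(out) <- indices
  out
}
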