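# From ROI time series to group-level similarity statistics: per-session
# connectivity (Pearson + Fisher-Z), Bonferroni binarization, paired-t
# selection of the treatment-responsive ("motor") subnetwork, pre/post
# dynamic networks, pairwise between-subject similarity, and the
# same-therapy (ST) vs different-therapy (DT) nonparametric comparison.
# A synthetic multivariate-normal cohort generator makes the whole stage
# testable without the (unavailable) patient fMRI data.

#' Build a connectivity matrix from ROI time series
#'
#' Pairwise Pearson correlations between all ROI signals, their two-sided
#' significance p-values (t reference distribution on `T_scan - 2` df), and
#' the variance-stabilizing Fisher-Z transform `z = atanh(r)`. Correlations
#' are clipped to `+-(1 - 1e-12)` before `atanh` so duplicated ROIs yield a
#' large finite z rather than infinity.
#'
#' @param roi_series Numeric matrix, `T_scan x n_roi` (`T_scan >= 3`), ROI
#'   names as column names.
#' @return A list of class `connectivity`: `r`, `z`, `p` (symmetric
#'   `n_roi x n_roi` matrices; diagonals 0, 0, 1), `n_scan`.
#' @export
build_connectivity <- function(roi_series) {
  x <- as.matrix(roi_series)
  if (nrow(x) < 3L) stop("need at least 3 scan volumes, got ", nrow(x))
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant ROI series: ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(x)
  rc <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  df <- nrow(x) - 2L
  tstat <- rc * sqrt(df / (1 - rc^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  z <- atanh(rc)
  diag(r) <- 0; diag(z) <- 0; diag(p) <- 1
  structure(list(r = r, z = z, p = p, n_scan = nrow(x)),
            class = "connectivity")
}

#' Bonferroni-thresholded binarization of a connectivity matrix
#'
#' An edge is kept iff its correlation p-value is strictly below
#' `alpha_level / m`, where `m = n_roi (n_roi - 1) / 2` is the number of
#' tests (for 20 ROIs, 0.05/190).
#'
#' @param conn A `connectivity` object.
#' @param alpha_level Family-wise error level before correction.
#' @return A binary symmetric snapshot matrix.
#' @export
binarize_bonferroni <- function(conn, alpha_level = 0.05) {
  stopifnot(inherits(conn, "connectivity"))
  n <- nrow(conn$p)
  thr <- alpha_level / n_edges(n)
  adj <- (conn$p < thr) * 1
  diag(adj) <- 0
  adj
}

#' Select the treatment-responsive edge subset by paired t-test
#'
#' For every edge, a two-sided paired t-test of the post- vs pre-treatment
#' Fisher-Z values across subjects; edges with `p < p_threshold`
#' (uncorrected -- a lenient threshold keeps the subnetwork from becoming
#' excessively small) are retained.
#'
#' @param pre_list,post_list Per-subject `connectivity` objects, paired by
#'   position.
#' @param p_threshold Two-sided uncorrected threshold (default 0.05).
#' @return A data frame with one row per retained edge: `i`, `j` (node
#'   indices, `i < j`), `t`, `p`; sorted by `p`. Edges whose paired
#'   differences are all zero are never retained.
#' @export
select_motor_network <- function(pre_list, post_list, p_threshold = 0.05) {
  if (length(pre_list) != length(post_list))
    stop("pre and post lists differ in length")
  if (length(pre_list) < 2L) stop("need at least 2 paired subjects")
  n <- nrow(pre_list[[1L]]$z)
  pairs <- edge_pairs(n)
  dz <- vapply(seq_along(pre_list), function(k)
    upper_vec(post_list[[k]]$z) - upper_vec(pre_list[[k]]$z),
    numeric(nrow(pairs)))                       # m x n_subj
  mns <- rowMeans(dz)
  sds <- apply(dz, 1L, stats::sd)
  ns <- ncol(dz)
  tstat <- ifelse(sds > 0, mns / (sds / sqrt(ns)), NA_real_)
  pval <- 2 * stats::pt(-abs(tstat), ns - 1L)
  keep <- which(!is.na(pval) & pval < p_threshold)
  out <- data.frame(i = pairs[keep, 1L], j = pairs[keep, 2L],
                    t = tstat[keep], p = pval[keep])
  out[order(out$p), , drop = FALSE]
}

#' Build a subject's pre/post dynamic motor network
#'
#' A `T = 2` dynamic network (timepoints pre, post) over the full ROI node
#' set, whose weights are the subject's Fisher-Z connectivity values on the
#' selected edge subset and 0 elsewhere. Negative z-values are retained:
#' the indices operate on weighted matrices and negative functional
#' connectivity is biologically meaningful.
#'
#' @param pre_conn,post_conn The subject's `connectivity` objects.
#' @param edges Edge subset as returned by [select_motor_network()] (only
#'   `i`/`j` are used).
#' @param node_labels Optional node labels for the resulting network.
#' @return A `dynamic_network` with `T = 2`.
#' @export
dynamic_motor_network <- function(pre_conn, post_conn, edges,
                                  node_labels = NULL) {
  n <- nrow(pre_conn$z)
  if (nrow(edges) == 0L) stop("empty edge subset: no motor network selected")
  w <- array(0, dim = c(2L, n, n))
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    w[1L, i, j] <- w[1L, j, i] <- pre_conn$z[i, j]
    w[2L, i, j] <- w[2L, j, i] <- post_conn$z[i, j]
  }
  dynamic_network(w, node_labels = node_labels,
                  time_labels = c("pre", "post"))
}

#' Pairwise between-subject similarity matrix
#'
#' Entry `(a, b)` is the chosen index between subject `a`'s and subject
#' `b`'s dynamic networks; with group sizes `n1` and `n2` this yields the
#' `n1 x n2` similarity matrix whose entries feed the ST/DT statistics.
#'
#' @param nets_a,nets_b Lists of `dynamic_network` objects (one per subject).
#' @param index_name One of `"dns"`, `"dnes"`, `"dice"`, `"jaccard"`,
#'   `"spectral"`, `"corr"`; traditional indices are averaged over
#'   timepoints and require binary networks (see [binarize()]).
#' @return An `length(nets_a) x length(nets_b)` numeric matrix.
#' @export
pairwise_similarity <- function(nets_a, nets_b, index_name = "dns") {
  fn <- switch(index_name,
               dns = function(a, b) dns(a, b)$value,
               dnes = function(a, b) dnes(a, b)$value,
               function(a, b)
                 traditional_dynamic_similarity(a, b, index_name)$value)
  out <- matrix(NA_real_, length(nets_a), length(nets_b))
  for (a in seq_along(nets_a))
    for (b in seq_along(nets_b))
      out[a, b] <- fn(nets_a[[a]], nets_b[[b]])
  out
}

# Signed-rank and rank-sum z statistics via the normal approximation
# (reported alongside exact p-values; ties get midranks).
wilcoxon_signed_z <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(0)
  v <- sum(rank(abs(d))[d > 0])
  (v - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
}

mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
}

cohen_d_one_sample <- function(x, mu) {
  s <- stats::sd(x)
  if (s == 0) {
    if (isTRUE(all.equal(mean(x), mu))) return(0)
    stop("Cohen's d undefined: zero-variance sample with mean != ", mu)
  }
  (mean(x) - mu) / s
}

cohen_d_pooled <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(0)
    stop("Cohen's d undefined: zero pooled variance with unequal means")
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Compare same-therapy and different-therapy similarity samples
#'
#' Three tests on the pairwise index values: a one-sample Wilcoxon
#' signed-rank test of each sample against the chance level 0.5 (exact
#' distribution for `n <= 25`, normal approximation with continuity
#' correction otherwise; two-sided), and a two-sided Mann-Whitney U test
#' between the two samples. Cohen's d accompanies each test: one-sample
#' `d = (mean - 0.5)/SD`, two-sample pooled-SD d.
#'
#' @param st_values,dt_values Numeric vectors of pairwise index values for
#'   the ST and DT pairings.
#' @param null_value Reference similarity level (0.5, the chance level of
#'   the normalized indices).
#' @return A list of class `group_comparison`: `st_values`, `dt_values`, and
#'   `st`, `dt`, `between`, each a list with `z`, `p`, `d`, `n`.
#' @export
compare_groups <- function(st_values, dt_values, null_value = 0.5) {
  one_sample <- function(x) {
    if (all(x == null_value))
      return(list(z = 0, p = 1, d = 0, n = length(x)))
    wt <- suppressWarnings(
      stats::wilcox.test(x, mu = null_value, exact = length(x) <= 25L,
                         correct = TRUE))
    list(z = wilcoxon_signed_z(x, null_value), p = wt$p.value,
         d = cohen_d_one_sample(x, null_value), n = length(x))
  }
  wt2 <- suppressWarnings(
    stats::wilcox.test(st_values, dt_values,
                       exact = length(st_values) <= 25L &&
                         length(dt_values) <= 25L,
                       correct = TRUE))
  structure(list(
    st_values = st_values, dt_values = dt_values,
    st = one_sample(st_values),
    dt = one_sample(dt_values),
    between = list(z = mann_whitney_z(st_values, dt_values), p = wt2$p.value,
                   d = cohen_d_pooled(st_values, dt_values),
                   n = c(length(st_values), length(dt_values)))),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(lab, s)
    cat(sprintf("  %-12s z = %6.3f, p = %-10.3g d = %6.3f (n = %s)\n",
                lab, s$z, s$p, s$d, paste(s$n, collapse = "x")))
  cat("<group_comparison>\n")
  fmt("ST vs 0.5:", x$st)
  fmt("DT vs 0.5:", x$dt)
  fmt("ST vs DT:", x$between)
  invisible(x)
}

## ---------------------------------------------------------------------------
## Synthetic cohort

# Default treatment-responsive edges: 9 connections among the first 6 ROIs,
# mirroring the size of the reported motor subnetwork.
default_effect_edges <- function() {
  cbind(i = c(1L, 1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L),
        j = c(2L, 3L, 4L, 3L, 5L, 6L, 5L, 6L, 6L))
}

# Clip a symmetric matrix to the positive-definite cone and renormalize to
# unit diagonal (smallest eigenvalue floored at eps).
pd_correlation <- function(m, eps = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, eps)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  (m2 + t(m2)) / 2
}

#' Generate a synthetic pre/post ROI-time-series cohort
#'
#' A stand-in for the (unavailable) stroke rehabilitation dataset: synthetic
#' data. Three groups -- `tdcs1` (`n1`), `tdcs2` (`n2`), `sham` (`n3`) --
#' each subject contributing a pre and a post session of `t_scan` scan
#' volumes over `n_roi` ROIs, drawn from a zero-mean multivariate normal.
#' All sessions share a cohort-level base correlation structure (a random
#' 3-factor model, with the designated `effect_edges` set to a baseline
#' correlation of 0.45) plus per-session Fisher-z jitter (SD 0.1). The two
#' treated groups receive a shared post-session decrease of `effect_size`
#' (correlation units) on `effect_edges`; sham receives none. Treated
#' subjects therefore share a reorganization pattern, which is exactly the
#' structure the ST-vs-DT comparison is designed to detect.
#'
#' @param n1,n2,n3 Group sizes (defaults 6, 5, 7, the post-exclusion cohort
#'   sizes of the reference study).
#' @param n_roi Number of ROIs (default 20).
#' @param t_scan Scan volumes per session (default 230).
#' @param effect_edges Integer matrix/data frame of `(i, j)` node pairs
#'   carrying the treatment effect (default: 9 edges among ROIs 1-6).
#' @param effect_size Absolute decrease in correlation on the effect edges
#'   post-treatment (default 0.25, a strong effect: paired-test Cohen's
#'   d of roughly 1.7 under the defaults).
#' @param seed Optional seed; the cohort is deterministic under a seed.
#' @return A list of class `cohort`: `sessions` (list of per-session lists
#'   with `subject_id`, `group`, `session` (`"pre"`/`"post"`),
#'   `roi_series`), `manifest` (subject/group data frame), plus the
#'   generation parameters.
#' @export
generate_synthetic_cohort <- function(n1 = 6L, n2 = 5L, n3 = 7L,
                                      n_roi = 20L, t_scan = 230L,
                                      effect_edges = default_effect_edges(),
                                      effect_size = 0.25, seed = NULL) {
  effect_edges <- as.matrix(effect_edges)
  if (max(effect_edges) > n_roi)
    stop("effect_edges reference ROIs beyond n_roi = ", n_roi)
  with_seed(seed, {
    roi_names <- sprintf("ROI%02d", seq_len(n_roi))
    loadings <- matrix(stats::rnorm(n_roi * 3L, sd = 0.4), n_roi, 3L)
    base <- tcrossprod(loadings) + diag(n_roi)
    base <- stats::cov2cor(base)
    for (k in seq_len(nrow(effect_edges)))
      base[effect_edges[k, 1L], effect_edges[k, 2L]] <-
        base[effect_edges[k, 2L], effect_edges[k, 1L]] <- 0.45
    base <- pd_correlation(base)

    groups <- rep(c("tdcs1", "tdcs2", "sham"), times = c(n1, n2, n3))
    ids <- sprintf("S%02d", seq_along(groups))
    sessions <- list()
    eff_lin <- effect_edges[, 1L] + (effect_edges[, 2L] - 1L) * n_roi
    for (s in seq_along(ids)) {
      for (ses in c("pre", "post")) {
        target <- base
        if (ses == "post" && groups[s] != "sham") {
          delta <- target[eff_lin] - effect_size
          target[eff_lin] <- delta
          target[(effect_edges[, 2L] - 1L) +
                   (effect_edges[, 1L] - 1L) * n_roi + 1L] <- delta
        }
        z <- atanh(pmin(pmax(target, -0.99), 0.99))
        jit <- matrix(stats::rnorm(n_roi * n_roi, sd = 0.1), n_roi, n_roi)
        jit <- (jit + t(jit)) / 2
        z <- z + jit
        r <- tanh(z)
        diag(r) <- 1
        r <- pd_correlation(r)
        x <- matrix(stats::rnorm(t_scan * n_roi), t_scan, n_roi) %*% chol(r)
        colnames(x) <- roi_names
        sessions[[paste(ids[s], ses, sep = "_")]] <-
          list(subject_id = ids[s], group = groups[s], session = ses,
               roi_series = x)
      }
    }
    structure(list(sessions = sessions,
                   manifest = data.frame(subject_id = ids, group = groups,
                                         stringsAsFactors = FALSE),
                   n_roi = n_roi, t_scan = t_scan,
                   effect_edges = effect_edges, effect_size = effect_size,
                   seed = seed),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat("<cohort> ", nrow(x$manifest), " subjects (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), "), ",
      x$n_roi, " ROIs, ", x$t_scan, " volumes/session\n", sep = "")
  invisible(x)
}

#' Run the full group-comparison pipeline on a cohort
#'
#' Per session: connectivity (Pearson + Fisher-Z). The treatment-responsive
#' edge subset is selected by paired t-test over the treated (tdcs1 +
#' tdcs2) subjects only; every subject's pre/post dynamic motor network is
#' then built on that subset, pairwise similarities are computed for the
#' same-therapy pairing (tdcs1 x tdcs2) and the different-therapy pairing
#' (tdcs1 x sham), and the two samples are compared with
#' [compare_groups()].
#'
#' @param cohort A `cohort` (see [generate_synthetic_cohort()]); any list
#'   with the same shape works, so real ROI tables can be substituted.
#' @param indices Character vector of indices to analyze.
#' @param p_threshold Edge-selection threshold (default 0.05).
#' @return A list of class `group_pipeline`: `edges` (selected subset),
#'   `st_matrix`/`dt_matrix` (per-index similarity matrices) and
#'   `comparisons` (per-index `group_comparison`).
#' @export
run_group_pipeline <- function(cohort, indices = c("dns", "dnes"),
                               p_threshold = 0.05) {
  man <- cohort$manifest
  conn <- lapply(cohort$sessions, function(s) build_connectivity(s$roi_series))
  get_conn <- function(id, ses) conn[[paste(id, ses, sep = "_")]]
  treated <- man$subject_id[man$group %in% c("tdcs1", "tdcs2")]
  edges <- select_motor_network(
    lapply(treated, get_conn, ses = "pre"),
    lapply(treated, get_conn, ses = "post"),
    p_threshold = p_threshold)
  nets <- lapply(man$subject_id, function(id)
    dynamic_motor_network(get_conn(id, "pre"), get_conn(id, "post"), edges))
  names(nets) <- man$subject_id
  g1 <- nets[man$group == "tdcs1"]
  g2 <- nets[man$group == "tdcs2"]
  g3 <- nets[man$group == "sham"]
  st_matrix <- lapply(indices, function(ix) pairwise_similarity(g1, g2, ix))
  dt_matrix <- lapply(indices, function(ix) pairwise_similarity(g1, g3, ix))
  names(st_matrix) <- names(dt_matrix) <- indices
  comparisons <- lapply(indices, function(ix)
    compare_groups(as.numeric(st_matrix[[ix]]), as.numeric(dt_matrix[[ix]])))
  names(comparisons) <- indices
  structure(list(edges = edges, st_matrix = st_matrix, dt_matrix = dt_matrix,
                 comparisons = comparisons),
            class = "group_pipeline")
}

#' @export
print.group_pipeline <- function(x, ...) {
  cat("<group_pipeline> ", nrow(x$edges), " selected edges; ",
      length(as.numeric(x$st_matrix[[1L]])), " ST pairs, ",
      length(as.numeric(x$dt_matrix[[1L]])), " DT pairs\n", sep = "")
  for (ix in names(x$comparisons)) {
    cat(toupper(ix), ":\n", sep = "")
    print(x$comparisons[[ix]])
  }
  invisible(x)
}
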