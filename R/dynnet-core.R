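# Core data model: dynamic networks as ordered stacks of symmetric weighted
# adjacency matrices, plus the two flattened views (long vector, per-edge
# time series) that the similarity indices are defined on.

SYMMETRY_TOL <- 1e-9

#' Construct a dynamic network
#'
#' A dynamic network is an ordered sequence of `T` undirected weighted
#' snapshots over a fixed node set: a `T x n x n` array of symmetric,
#' zero-diagonal adjacency matrices. Entry `[t, i, j]` is the connectivity
#' strength (dimensionless) between nodes `i` and `j` at timepoint `t`.
#'
#' @param weights A `T x n x n` numeric array, or a list of `n x n` symmetric
#'   matrices (one per timepoint, in temporal order).
#' @param node_labels Optional character vector of `n` node identifiers.
#' @param time_labels Optional character vector of `T` timepoint identifiers.
#'
#' @return An object of class `dynamic_network` with elements `weights`
#'   (`T x n x n` array), `node_labels` and `time_labels`.
#'
#' @details Every snapshot must be symmetric with zero diagonal to within
#'   `1e-9` (absolute), all weights finite, `n >= 2`, `T >= 1`. Self-loops
#'   are excluded: brain connectomes carry no self-connectivity, and the
#'   indices are defined on the off-diagonal edge universe.
#'
#' @examples
#' m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
#' net <- dynamic_network(list(m, 2 * m))
#' net
#' @export
dynamic_network <- function(weights, node_labels = NULL, time_labels = NULL) {
  if (is.list(weights)) {
    if (length(weights) == 0L)
      stop("`weights` must contain at least one timepoint matrix")
    n <- nrow(weights[[1L]])
    arr <- array(NA_real_, dim = c(length(weights), n, n))
    for (t in seq_along(weights)) {
      wt <- as.matrix(weights[[t]])
      if (!all(dim(wt) == c(n, n)))
        stop("timepoint ", t, ": matrix is ", nrow(wt), "x", ncol(wt),
             " but timepoint 1 is ", n, "x", n)
      arr[t, , ] <- wt
    }
    weights <- arr
  }
  if (!is.array(weights) || length(dim(weights)) != 3L)
    stop("`weights` must be a T x n x n array or a list of n x n matrices")
  storage.mode(weights) <- "double"
  tt <- dim(weights)[1L]
  n <- dim(weights)[2L]
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  if (is.null(time_labels)) time_labels <- paste0("t", seq_len(tt))
  net <- structure(
    list(weights = weights,
         node_labels = as.character(node_labels),
         time_labels = as.character(time_labels)),
    class = "dynamic_network")
  validate_dynamic_network(net)
  net
}

#' Validate a dynamic network
#'
#' Checks the `dynamic_network` invariants: `n >= 2`, `T >= 1`, label lengths,
#' finite weights, and symmetry with zero diagonal to within `tol`.
#'
#' @param net A `dynamic_network`.
#' @param tol Absolute tolerance for the symmetry and zero-diagonal checks.
#' @return `net`, invisibly. Errors on any violation.
#' @export
validate_dynamic_network <- function(net, tol = SYMMETRY_TOL) {
  stopifnot(inherits(net, "dynamic_network"))
  d <- dim(net$weights)
  if (d[2L] != d[3L]) stop("snapshots must be square, got ", d[2L], "x", d[3L])
  if (d[2L] < 2L) stop("a network needs at least 2 nodes, got ", d[2L])
  if (d[1L] < 1L) stop("a dynamic network needs at least 1 timepoint")
  if (length(net$node_labels) != d[2L])
    stop("node_labels length ", length(net$node_labels),
         " does not match n = ", d[2L])
  if (length(net$time_labels) != d[1L])
    stop("time_labels length ", length(net$time_labels),
         " does not match T = ", d[1L])
  if (!all(is.finite(net$weights))) stop("all weights must be finite")
  for (t in seq_len(d[1L])) {
    wt <- net$weights[t, , ]
    if (max(abs(wt - t(wt))) > tol)
      stop("timepoint ", t, ": snapshot is not symmetric (tolerance ",
           format(tol), ")")
    if (max(abs(diag(wt))) > tol)
      stop("timepoint ", t, ": snapshot has a nonzero diagonal (tolerance ",
           format(tol), ")")
  }
  invisible(net)
}

#' @export
print.dynamic_network <- function(x, ...) {
  d <- dim(x$weights)
  cat("<dynamic_network> ", d[2L], " nodes, ", d[1L], " timepoints, ",
      n_edges(d[2L]), " edges per snapshot\n", sep = "")
  cat("  weight range: [", format(min(x$weights), digits = 4), ", ",
      format(max(x$weights), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Number of timepoints / nodes of a dynamic network
#' @param net A `dynamic_network`.
#' @return Integer scalar.
#' @export
n_timepoints <- function(net) dim(net$weights)[1L]

#' @rdname n_timepoints
#' @export
n_nodes <- function(net) dim(net$weights)[2L]

# m = n(n-1)/2 off-diagonal undirected edges
n_edges <- function(n) as.integer(n * (n - 1L) / 2L)

#' Canonical edge ordering
#'
#' Returns the node-pair index table of the canonical edge ordering used by
#' all flattening operations: upper triangle excluding the diagonal, row-major
#' (`(1,2), (1,3), ..., (1,n), (2,3), ...`).
#'
#' @param n Number of nodes.
#' @return An `m x 2` integer matrix of `(i, j)` pairs with `i < j`,
#'   `m = n(n-1)/2`.
#' @export
edge_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

# Row-major upper triangle of one symmetric matrix, as a vector.
# t(m)[lower.tri(m)] walks the lower triangle of t(m) column-major, which is
# exactly the upper triangle of m row-major.
upper_vec <- function(m) t(m)[lower.tri(m)]

# Inverse: fold an edge vector (canonical order) into a symmetric matrix.
edges_to_matrix <- function(values, n) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- values   # fills lower triangle column-major = canonical
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Flatten a dynamic network into its long vector
#'
#' Reshapes each snapshot into its edge vector (upper triangle excluding the
#' diagonal, row-major) and concatenates the `T` vectors end-to-end along the
#' time axis. This long vector `V` carries all the information of the network
#' and is the object on which the DNS index is defined.
#'
#' @param net A `dynamic_network`.
#' @return A numeric vector of length `T * m`, `m = n(n-1)/2`, with attributes
#'   `m` and `n_timepoints`.
#' @seealso [edge_time_series()] for the transposed (edge-major) view.
#' @examples
#' m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
#' flatten_long_vector(dynamic_network(list(m)))  # 1 2 3
#' @export
flatten_long_vector <- function(net) {
  validate_dynamic_network(net)
  tt <- n_timepoints(net)
  v <- unlist(lapply(seq_len(tt), function(t) upper_vec(net$weights[t, , ])),
              use.names = FALSE)
  structure(v, m = n_edges(n_nodes(net)), n_timepoints = tt)
}

#' Extract the per-edge time series of a dynamic network
#'
#' For each of the `m = n(n-1)/2` node pairs, the `T`-length trajectory of its
#' weight. These edge series are the objects on which the DNES index is
#' defined.
#'
#' @param net A `dynamic_network`.
#' @return A `T x m` numeric matrix; column order is the canonical edge order
#'   of [edge_pairs()], with columns named `"i-j"` and an attribute
#'   `node_pairs` holding the index table.
#' @export
edge_time_series <- function(net) {
  validate_dynamic_network(net)
  tt <- n_timepoints(net)
  n <- n_nodes(net)
  pairs <- edge_pairs(n)
  ets <- matrix(flatten_long_vector(net), nrow = tt, byrow = TRUE)
  colnames(ets) <- paste0(pairs[, 1L], "-", pairs[, 2L])
  attr(ets, "node_pairs") <- pairs
  ets
}

# Shape alignment used by every pairwise index.
check_aligned <- function(a, b, strict_labels = FALSE) {
  if (n_nodes(a) != n_nodes(b) || n_timepoints(a) != n_timepoints(b))
    stop("networks are not aligned: ", n_nodes(a), " nodes x ",
         n_timepoints(a), " timepoints vs ", n_nodes(b), " nodes x ",
         n_timepoints(b), " timepoints")
  if (strict_labels && !identical(a$node_labels, b$node_labels))
    stop("node label lists differ; node correspondence is by position ",
         "(use strict_labels = FALSE to compare by position anyway)")
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## File I/O
##
## Stacked-text format (.dnt):
##   optional leading "# ..." comment lines; "# nodes: a b c" carries labels
##   header line: "n T"
##   then T whitespace-delimited n x n blocks separated by blank lines.

#' Read a dynamic network from disk
#'
#' Two plain-text layouts are supported. `"stacked"`: one file with optional
#' leading `#` comment lines (a `# nodes: ...` comment carries node labels), a
#' header line `"n T"`, then `T` whitespace-delimited `n x n` blocks separated
#' by blank lines. `"manifest"`: a manifest file listing one delimited
#' (comma or whitespace) square-matrix file per line, one timepoint each,
#' paths relative to the manifest.
#'
#' @param path Path to the stacked file or the manifest.
#' @param format `"stacked"` or `"manifest"`.
#' @return A `dynamic_network`.
#' @export
read_dynamic_network <- function(path, format = c("stacked", "manifest")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "manifest") return(read_dynnet_manifest(path))
  lines <- readLines(path)
  node_labels <- NULL
  k <- 1L
  while (k <= length(lines) && grepl("^\\s*#", lines[k])) {
    if (grepl("^\\s*#\\s*nodes:", lines[k]))
      node_labels <- strsplit(trimws(sub("^\\s*#\\s*nodes:", "", lines[k])),
                              "\\s+")[[1L]]
    k <- k + 1L
  }
  if (k > length(lines))
    stop("parse error at line ", k, ": missing 'n T' header")
  hdr <- parse_numeric_tokens(lines[k], k)
  if (length(hdr) != 2L || any(hdr != round(hdr)) || any(hdr < 1))
    stop("parse error at line ", k, ": header must be two integers 'n T'")
  n <- as.integer(hdr[1L]); tt <- as.integer(hdr[2L])
  rows <- vector("list", tt)
  t_cur <- 0L
  r_cur <- 0L
  block <- NULL
  for (ln in seq(k + 1L, length.out = max(0L, length(lines) - k))) {
    line <- lines[ln]
    if (grepl("^\\s*(#|$)", line)) next
    vals <- parse_numeric_tokens(line, ln)
    if (length(vals) != n)
      stop("parse error at line ", ln, ": expected ", n,
           " values per row, got ", length(vals))
    if (r_cur == 0L) {
      t_cur <- t_cur + 1L
      if (t_cur > tt)
        stop("parse error at line ", ln, ": found more than ", tt,
             " blocks declared in the header")
      block <- matrix(NA_real_, n, n)
    }
    r_cur <- r_cur + 1L
    block[r_cur, ] <- vals
    if (r_cur == n) {
      rows[[t_cur]] <- block
      r_cur <- 0L
    }
  }
  if (r_cur != 0L)
    stop("parse error at line ", length(lines), ": block ", t_cur,
         " is incomplete (", r_cur, " of ", n, " rows)")
  if (t_cur != tt)
    stop("parse error at line ", length(lines), ": header declares ", tt,
         " blocks but found ", t_cur)
  dynamic_network(rows, node_labels = node_labels)
}

parse_numeric_tokens <- function(line, line_no) {
  toks <- strsplit(trimws(line), "[,[:space:]]+")[[1L]]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) {
    bad <- toks[which(is.na(vals))[1L]]
    stop("parse error at line ", line_no, ": non-numeric token '", bad, "'")
  }
  vals
}

read_dynnet_manifest <- function(path) {
  files <- readLines(path)
  files <- trimws(files[!grepl("^\\s*(#|$)", files)])
  if (length(files) == 0L) stop("manifest '", path, "' lists no files")
  base <- dirname(path)
  mats <- lapply(files, function(f) {
    fp <- if (file.exists(f)) f else file.path(base, f)
    if (!file.exists(fp)) stop("manifest entry not found: ", f)
    lines <- readLines(fp)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    do.call(rbind, lapply(seq_along(lines),
                          function(i) parse_numeric_tokens(lines[i], i)))
  })
  dynamic_network(mats)
}

#' Write a dynamic network to disk
#'
#' Inverse of [read_dynamic_network()]; `write` then `read` reproduces the
#' weights to better than `1e-12`.
#'
#' @param net A `dynamic_network`.
#' @param path Output path (stacked format) or manifest path (manifest
#'   format; per-timepoint files are written next to it).
#' @param format `"stacked"` or `"manifest"`.
#' @return `path`, invisibly.
#' @export
write_dynamic_network <- function(net, path, format = c("stacked", "manifest")) {
  format <- match.arg(format)
  validate_dynamic_network(net)
  tt <- n_timepoints(net); n <- n_nodes(net)
  fmt_row <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  if (format == "stacked") {
    out <- c(paste("# nodes:", paste(net$node_labels, collapse = " ")),
             paste(n, tt))
    for (t in seq_len(tt)) {
      out <- c(out, apply(net$weights[t, , , drop = TRUE], 1L, fmt_row), "")
    }
    write_atomically(out, path)
  } else {
    stem <- sub("\\.[^.]*$", "", basename(path))
    files <- sprintf("%s_t%03d.txt", stem, seq_len(tt))
    for (t in seq_len(tt)) {
      write_atomically(apply(net$weights[t, , , drop = TRUE], 1L, fmt_row),
                       file.path(dirname(path), files[t]))
    }
    write_atomically(files, path)
  }
  invisible(path)
}

# All CLI/file outputs go through here: write to a sibling temp file, then
# rename, so readers never observe a half-written file.
write_atomically <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read an ROI time-series table
#'
#' Delimited text (comma, tab or whitespace), one row per scan volume, one
#' column per ROI, with a header row of ROI names.
#'
#' @param path Path to the table.
#' @return A numeric matrix (`T_scan x n_roi`) with ROI names as column names.
#' @export
read_roi_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "",
                          check.names = FALSE, comment.char = "#")
  if (any(!vapply(df, is.numeric, logical(1L))))
    stop("non-numeric column(s) in ROI table: ",
         paste(names(df)[!vapply(df, is.numeric, logical(1L))], collapse = ", "))
  as.matrix(df)
}

#' Write an ROI time-series table
#' @param series Numeric matrix, `T_scan x n_roi`, ROI names as column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_series <- function(series, path) {
  lines <- c(paste(colnames(series), collapse = "\t"),
             apply(series, 1L, function(r)
               paste(sprintf("%.10g", r), collapse = "\t")))
  write_atomically(lines, path)
}
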