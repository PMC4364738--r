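#' Construct a sparse positive weighted network
#'
#' @param n_nodes number of nodes N (isolated nodes allowed).
#' @param edges data.frame with integer columns \code{i}, \code{j}
#'   (1-based, \code{i < j} enforced by sorting) and numeric \code{w} in
#'   (0, 1].
#' @return object of class \code{weighted_network} with fields
#'   \code{n_nodes}, \code{edges}, \code{K}.
#' @export
weighted_network <- function(n_nodes, edges) {
  n_nodes <- as.integer(n_nodes)
  if (nrow(edges) > 0) {
    i <- pmin(edges$i, edges$j)
    j <- pmax(edges$i, edges$j)
    edges <- data.frame(i = as.integer(i), j = as.integer(j), w = edges$w)
    if (any(edges$i == edges$j)) stop("self-loops are not allowed")
    if (any(edges$w <= 0)) stop("weights must be strictly positive")
    if (anyDuplicated(edges[, c("i", "j")])) stop("duplicate edges")
    if (any(edges$j > n_nodes)) stop("edge endpoint exceeds n_nodes")
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(i = integer(), j = integer(), w = numeric())
  }
  structure(list(n_nodes = n_nodes, edges = edges, K = nrow(edges)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: N = %d nodes, K = %d edges\n",
              x$n_nodes, x$K))
  invisible(x)
}

#' Dense symmetric adjacency matrix of a network
#' @param net a \code{weighted_network}.
#' @return n x n numeric matrix, zero diagonal.
#' @export
adjacency_matrix <- function(net) {
  a <- matrix(0, net$n_nodes, net$n_nodes)
  if (net$K > 0) {
    idx <- cbind(net$edges$i, net$edges$j)
    a[idx] <- net$edges$w
    a[idx[, 2:1, drop = FALSE]] <- net$edges$w
  }
  a
}

#' Build a weighted_network from a symmetric matrix
#' @param a symmetric matrix; entries > 0 above the diagonal become edges.
#' @return \code{weighted_network}.
#' @export
network_from_matrix <- function(a) {
  a <- as.matrix(a)
  up <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  weighted_network(nrow(a),
                   data.frame(i = up[, 1], j = up[, 2], w = a[up]))
}

as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = net$n_nodes, directed = FALSE)
  if (net$K > 0) {
    g <- igraph::add_edges(g, rbind(net$edges$i, net$edges$j))
    igraph::E(g)$weight <- net$edges$w
  }
  g
}

#' Pearson correlation matrix of ROI time series
#'
#' @param ts matrix, time points x ROIs; at least 3 rows, no missing values.
#'   Constant columns yield r = 0 against everything, with a warning.
#' @return object of class \code{connectivity_matrix}: list with the
#'   correlation matrix \code{r}, \code{n_rois}, and
#'   \code{n_effective_timepoints} used downstream for significance.
#' @export
pearson_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  if (anyNA(ts)) stop("time series contain missing values")
  if (nrow(ts) < 3) stop("need at least 3 time points")
  const <- apply(ts, 2, function(x) stats::sd(x) == 0)
  r <- suppressWarnings(stats::cor(ts))
  if (any(const)) {
    warning(sprintf("%d constant column(s); correlations set to 0",
                    sum(const)))
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  structure(list(r = r, n_rois = ncol(ts),
                 n_effective_timepoints = nrow(ts)),
            class = "connectivity_matrix")
}

# two-sided p for a correlation under the t transform
correlation_p <- function(r, df) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
  2 * stats::pt(t, df, lower.tail = FALSE)
}

#' Bonferroni-threshold a correlation matrix into a weighted network
#'
#' Each of the M = n(n-1)/2 unique pairs gets a two-sided p-value from the
#' t transform of r with df = effective time points - 2; pairs with
#' p < alpha / M survive, negative correlations are then excluded, and the
#' surviving r values become edge weights.
#'
#' @param cm a \code{connectivity_matrix}.
#' @param alpha family-wise level before Bonferroni division (default 0.05).
#' @param df_override optional degrees of freedom replacing the default.
#' @return \code{weighted_network}.
#' @export
threshold_to_weighted_network <- function(cm, alpha = 0.05,
                                          df_override = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"), alpha > 0, alpha < 1)
  df <- if (is.null(df_override)) cm$n_effective_timepoints - 2 else df_override
  if (df <= 2) stop("degrees of freedom must exceed 2")
  n <- cm$n_rois
  m <- n * (n - 1) / 2
  up <- which(upper.tri(cm$r), arr.ind = TRUE)
  r <- cm$r[up]
  p <- correlation_p(r, df)
  keep <- p < alpha / m & r > 0
  weighted_network(n, data.frame(i = up[keep, 1], j = up[keep, 2],
                                 w = pmin(r[keep], 1)))
}

#' Band-corrected effective degrees of freedom
#'
#' After band-pass filtering to \code{[low_hz, high_hz]}, neighbouring
#' volumes are no longer independent; the effective number of independent
#' samples is approximately the number of retained Fourier components,
#' \code{n * (high_hz - low_hz) / nyquist}. Using the nominal df makes the
#' correlation significance test anticonservative on filtered series.
#'
#' @param n_timepoints retained volumes.
#' @param tr_seconds repetition time.
#' @param low_hz,high_hz pass band.
#' @return effective df for the r-to-t test (effective n minus 2).
#' @export
effective_df <- function(n_timepoints, tr_seconds, low_hz = 0.01,
                         high_hz = 0.1) {
  nyquist <- 1 / (2 * tr_seconds)
  max(round(n_timepoints * (high_hz - low_hz) / nyquist) - 2, 3)
}

#' Per-edge Bonferroni threshold
#' @param n_rois nodes; @param alpha level (default 0.05).
#' @return alpha / (n(n-1)/2).
#' @export
bonferroni_edge_threshold <- function(n_rois, alpha = 0.05) {
  alpha / (n_rois * (n_rois - 1) / 2)
}

#' Fisher-z average of correlation matrices
#'
#' Elementwise atanh, mean across subjects, tanh back. Off-diagonal entries
#' with |r| >= 1 are clipped to +/-0.999999 with a warning. When the inputs
#' are thresholded (sparse) matrices, absent entries are zeros and enter the
#' average as z = 0.
#'
#' @param matrices list of \code{connectivity_matrix} objects or plain
#'   symmetric matrices with matching dimension.
#' @return \code{connectivity_matrix} of the group average;
#'   \code{n_effective_timepoints} is the minimum across inputs (NA for
#'   plain matrices).
#' @export
group_mean_network <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  mats <- lapply(matrices, function(m)
    if (inherits(m, "connectivity_matrix")) m$r else as.matrix(m))
  n <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 0L) == n)) stop("matrix dimensions differ")
  zsum <- matrix(0, n, n)
  for (m in mats) {
    off <- abs(m) >= 1 & row(m) != col(m)
    if (any(off)) {
      warning("off-diagonal |r| >= 1 clipped to 0.999999")
      m[off] <- sign(m[off]) * 0.999999
    }
    diag(m) <- 0
    zsum <- zsum + atanh(m)
  }
  r <- tanh(zsum / length(mats))
  diag(r) <- 1
  ne <- vapply(matrices, function(m)
    if (inherits(m, "connectivity_matrix")) m$n_effective_timepoints
    else NA_integer_, NA_integer_)
  structure(list(r = r, n_rois = n,
                 n_effective_timepoints = suppressWarnings(min(ne))),
            class = "connectivity_matrix")
}

#' Backbone extraction by locally adaptive sparsification
#'
#' Rank-based local significance filter. Each node ranks its incident
#' positive weights in decreasing order (ties share the best rank). Under
#' the node-local null that incident ranks are exchangeable, an edge at
#' rank t of k_i has tail probability t / k_i of ranking that high by
#' chance; the edge is locally significant for node i when
#' \code{t / k_i <= local_alpha}. An edge is kept when it is its endpoint's
#' single strongest edge, or locally significant from either endpoint (OR
#' rule) — so every node retains its dominant connection and hubs retain
#' their top fraction, preserving structure at every weight scale. If the
#' kept graph is connected on fewer than 95\% of the non-isolated nodes,
#' \code{local_alpha} is doubled (up to 0.5) with a warning.
#'
#' The source names only a "nonparametric sparsification" for this step;
#' this filter is a reconstruction with the stated contract.
#'
#' @param cm \code{connectivity_matrix} (or plain symmetric matrix); only
#'   positive entries are considered.
#' @param local_alpha node-local significance level (default 0.05).
#' @return \code{weighted_network}.
#' @export
extract_backbone <- function(cm, local_alpha = 0.05) {
  a <- if (inherits(cm, "connectivity_matrix")) cm$r else as.matrix(cm)
  diag(a) <- 0
  a[a < 0] <- 0
  if (all(a == 0)) stop("no positive entries to sparsify")
  n <- nrow(a)
  deg <- rowSums(a > 0)
  # min-rank of each positive entry within its row (descending weight)
  rk <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    if (!length(nb)) next
    w <- a[i, nb]
    rk[i, nb] <- rank(-w, ties.method = "min")
  }
  up <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  w <- a[up]
  ri <- rk[up]
  rj <- rk[up[, 2:1, drop = FALSE]]
  ki <- deg[up[, 1]]
  kj <- deg[up[, 2]]

  la <- local_alpha
  repeat {
    keep <- ri == 1 | rj == 1 | ri / ki <= la | rj / kj <= la
    net <- weighted_network(n, data.frame(i = up[keep, 1], j = up[keep, 2],
                                          w = w[keep]))
    active <- unique(c(up[, 1], up[, 2]))
    comp <- igraph::components(as_igraph(net))
    frac <- max(comp$csize) / length(active)
    if (frac >= 0.95 || la >= 0.5) break
    la <- min(la * 2, 0.5)
    warning(sprintf("backbone disconnected; relaxing local_alpha to %.3g", la))
  }
  net
}

#' Seed-based connectivity map
#'
#' @param ts time points x ROIs matrix.
#' @param seed_roi column index of the seed region.
#' @return vector of Pearson r of the seed against every ROI
#'   (self-correlation 1).
#' @export
seed_connectivity_map <- function(ts, seed_roi) {
  ts <- as.matrix(ts)
  if (seed_roi < 1 || seed_roi > ncol(ts)) stop("invalid seed ROI")
  s <- ts[, seed_roi]
  if (stats::sd(s) == 0) stop("seed time series is constant")
  r <- as.vector(stats::cor(s, ts))
  r[seed_roi] <- 1
  r
}
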