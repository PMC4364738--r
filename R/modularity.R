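#' Weighted modularity of a given partition
#'
#' \deqn{Q = \sum_s [ w_s / W - (W_s / 2W)^2 ]}
#' where W is the total network weight (each edge counted once), w_s the
#' intra-module weight of module s (each edge once) and W_s the sum of nodal
#' strengths in s (each incident edge counted at both endpoints). This is
#' the standard Newman weighted modularity: one module gives Q = 0, two
#' disconnected equal cliques labeled by clique give Q = 0.5.
#'
#' @param net \code{weighted_network} with positive total weight.
#' @param labels integer module label per node.
#' @return object of class \code{partition}: \code{labels},
#'   \code{n_modules}, \code{q}, and the per-module terms \code{w_s},
#'   \code{W_s}, plus total weight \code{W}.
#' @export
modularity_q <- function(net, labels) {
  labels <- as.integer(factor(labels))
  if (length(labels) != net$n_nodes) stop("one label per node required")
  w_total <- sum(net$edges$w)
  if (w_total == 0) stop("total network weight is zero")
  n_mod <- max(labels)
  strength <- numeric(net$n_nodes)
  w_s <- numeric(n_mod)
  for (r in seq_len(net$K)) {
    i <- net$edges$i[r]; j <- net$edges$j[r]; w <- net$edges$w[r]
    strength[i] <- strength[i] + w
    strength[j] <- strength[j] + w
    if (labels[i] == labels[j]) w_s[labels[i]] <- w_s[labels[i]] + w
  }
  big_w_s <- vapply(seq_len(n_mod), function(s) sum(strength[labels == s]), 0)
  q <- sum(w_s / w_total - (big_w_s / (2 * w_total))^2)
  structure(list(labels = labels, n_modules = n_mod, q = q,
                 w_s = w_s, W_s = big_w_s, W = w_total),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d modules, Q = %.4f, sizes: %s\n",
              x$n_modules, x$q, paste(tabulate(x$labels), collapse = "/")))
  invisible(x)
}

# delta-Q (unnormalized, s^T B s form) of flipping node i given q_i = (B s)_i
# used by the Kernighan-Lin style refinement below
kl_refine <- function(b, s) {
  repeat {
    q_vec <- b %*% s
    gains <- -4 * s * q_vec + 4 * diag(b)
    best <- which.max(gains)
    if (gains[best] <= 1e-12) break
    s[best] <- -s[best]
  }
  s
}

# split one group (indices into the component) by the leading eigenvector of
# the generalized modularity matrix; returns NULL when indivisible
spectral_split <- function(b_full, idx, m2) {
  bg <- b_full[idx, idx, drop = FALSE]
  diag(bg) <- diag(bg) - rowSums(bg)
  ev <- eigen(bg, symmetric = TRUE)
  v <- ev$vectors[, 1]
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1]] < 0) v <- -v  # deterministic sign
  if (ev$values[1] <= 1e-10) return(NULL)
  s <- ifelse(v >= 0, 1, -1)
  s <- kl_refine(bg, s)
  dq <- as.numeric(t(s) %*% bg %*% s) / (2 * m2)
  if (dq <= 1e-10 || all(s == s[1])) return(NULL)
  s
}

#' Module detection by spectral modularity optimization
#'
#' Recursive leading-eigenvector bisection of the weighted modularity
#' matrix, with greedy single-node (Kernighan-Lin style) refinement after
#' each split; recursion stops when no split increases Q. Connected
#' components are partitioned independently; the eigenvector sign is fixed
#' (first nonzero component positive) so the result is deterministic.
#'
#' @param net \code{weighted_network}.
#' @return \code{partition} (see \code{\link{modularity_q}}).
#' @export
spectral_partition <- function(net) {
  labels <- integer(net$n_nodes)
  comp <- igraph::components(as_igraph(net))
  next_label <- 0L
  for (c_id in seq_len(comp$no)) {
    nodes <- which(comp$membership == c_id)
    if (length(nodes) == 1) {
      next_label <- next_label + 1L
      labels[nodes] <- next_label
      next
    }
    sub <- induced_subnetwork(net, nodes)
    a <- adjacency_matrix(sub)
    k <- rowSums(a)
    m2 <- sum(k)
    b <- a - outer(k, k) / m2

    groups <- list(seq_along(nodes))
    final <- list()
    while (length(groups)) {
      g <- groups[[1]]
      groups <- groups[-1]
      s <- if (length(g) >= 2) spectral_split(b, g, m2) else NULL
      if (is.null(s)) {
        final[[length(final) + 1]] <- g
      } else {
        groups <- c(groups, list(g[s > 0]), list(g[s < 0]))
      }
    }
    for (g in final) {
      next_label <- next_label + 1L
      labels[nodes[g]] <- next_label
    }
  }
  modularity_q(net, labels)
}

#' Per-subject intra- and inter-module connectivity strength
#'
#' For each subject network, the mean edge weight within every module and
#' between every module pair, averaging over all possible node pairs
#' (absent edges count as 0). The partition is the reference partition from
#' the group backbone.
#'
#' @param nets list of \code{weighted_network} (one per subject), all on the
#'   same node set as the partition.
#' @param partition \code{partition} (reference module labels).
#' @return data.frame, one row per subject, columns \code{intra_<s>} then
#'   \code{inter_<s>_<t>}.
#' @export
module_connectivity <- function(nets, partition) {
  labels <- partition$labels
  n_mod <- partition$n_modules
  sizes <- tabulate(labels, n_mod)
  pair_names <- c(sprintf("intra_%d", seq_len(n_mod)))
  combs <- if (n_mod >= 2) utils::combn(n_mod, 2) else matrix(0, 2, 0)
  pair_names <- c(pair_names,
                  apply(combs, 2, function(p) sprintf("inter_%d_%d", p[1], p[2])))
  out <- matrix(0, length(nets), length(pair_names),
                dimnames = list(NULL, pair_names))
  for (si in seq_along(nets)) {
    net <- nets[[si]]
    stopifnot(net$n_nodes == length(labels))
    li <- labels[net$edges$i]
    lj <- labels[net$edges$j]
    for (s in seq_len(n_mod)) {
      denom <- sizes[s] * (sizes[s] - 1) / 2
      out[si, s] <- if (denom > 0)
        sum(net$edges$w[li == s & lj == s]) / denom else 0
    }
    if (ncol(combs) > 0) for (cix in seq_len(ncol(combs))) {
      s <- combs[1, cix]; t <- combs[2, cix]
      cross <- (li == s & lj == t) | (li == t & lj == s)
      out[si, n_mod + cix] <- sum(net$edges$w[cross]) / (sizes[s] * sizes[t])
    }
  }
  as.data.frame(out)
}

#' Topology of each module's induced subgraph
#'
#' Raw and null-normalized efficiencies of the subgraph induced by each
#' module with at least 3 nodes; smaller modules are skipped with a warning.
#'
#' @param net \code{weighted_network}.
#' @param partition reference \code{partition}.
#' @param n_nulls ensemble size for normalization (default 100; 0 skips
#'   normalization).
#' @return data.frame with one row per computed module.
#' @export
module_level_metrics <- function(net, partition, n_nulls = 100) {
  rows <- list()
  for (s in seq_len(partition$n_modules)) {
    nodes <- which(partition$labels == s)
    if (length(nodes) < 3) {
      warning(sprintf("module %d has < 3 nodes; skipped", s))
      next
    }
    sub <- induced_subnetwork(net, nodes)
    if (n_nulls > 0 && sub$K >= 2) {
      gm <- normalized_efficiencies(sub, n_nulls)
      rows[[length(rows) + 1]] <- data.frame(
        module = s, n_nodes = length(nodes), e_glob = gm$e_glob,
        e_loc = gm$e_loc, e_glob_norm = gm$e_glob_norm,
        e_loc_norm = gm$e_loc_norm)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        module = s, n_nodes = length(nodes),
        e_glob = if (sub$n_nodes >= 2) global_efficiency(sub) else 0,
        e_loc = local_efficiency(sub),
        e_glob_norm = NA_real_, e_loc_norm = NA_real_)
    }
  }
  do.call(rbind, rows)
}
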