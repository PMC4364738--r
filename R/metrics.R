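#' Shortest path lengths over inverse-weight edge lengths
#'
#' Edge length is the reciprocal of the edge weight, so a strong functional
#' connection is a short functional distance. Dijkstra from every source;
#' unreachable pairs are +Inf, the diagonal 0.
#'
#' @param net a \code{weighted_network}.
#' @return n x n symmetric matrix of path lengths.
#' @export
shortest_path_lengths <- function(net) {
  if (net$K == 0) {
    d <- matrix(Inf, net$n_nodes, net$n_nodes)
    diag(d) <- 0
    return(d)
  }
  g <- as_igraph(net)
  igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                    algorithm = "dijkstra")
}

#' Global efficiency
#'
#' Mean of 1/d_ij over ordered pairs i != j, with 1/Inf = 0 for
#' disconnected pairs: the capacity for parallel information transfer over
#' the whole network.
#'
#' @param net \code{weighted_network} with at least 2 nodes.
#' @return scalar efficiency (>= 0; 1 for a complete unit-weight graph).
#' @export
global_efficiency <- function(net) {
  if (net$n_nodes < 2) stop("global efficiency needs at least 2 nodes")
  d <- shortest_path_lengths(net)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (net$n_nodes * (net$n_nodes - 1))
}

#' Local efficiency
#'
#' Average over nodes of the global efficiency of each node's
#' neighbor-induced subgraph (original weights retained between neighbors);
#' measures fault tolerance when the index node is removed. Nodes with
#' fewer than 2 neighbors contribute 0.
#'
#' @param net \code{weighted_network}.
#' @return scalar.
#' @export
local_efficiency <- function(net) {
  if (net$n_nodes < 1) stop("empty network")
  if (net$K == 0) return(0)
  a <- adjacency_matrix(net)
  total <- 0
  for (v in seq_len(net$n_nodes)) {
    nb <- which(a[v, ] > 0)
    m <- length(nb)
    if (m < 2) next
    # dense min-plus closure on the neighbor submatrix: exact, and much
    # cheaper than spawning a graph object per node
    sub <- a[nb, nb, drop = FALSE]
    d <- matrix(Inf, m, m)
    pos <- sub > 0
    d[pos] <- 1 / sub[pos]
    diag(d) <- 0
    for (k in seq_len(m)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
    inv <- 1 / d
    diag(inv) <- 0
    total <- total + sum(inv) / (m * (m - 1))
  }
  total / net$n_nodes
}

#' Nodal efficiency and strength
#'
#' Per node i, the mean of 1/d_ij over the other nodes: the information
#' propagation ability of the node. High values mark hub-like regions. The
#' node's strength (sum of incident weights) is returned alongside. The
#' mean of nodal efficiency over nodes equals the global efficiency.
#'
#' @param net \code{weighted_network} with >= 2 nodes.
#' @return data.frame with columns \code{node}, \code{e_nodal},
#'   \code{strength}.
#' @export
nodal_efficiency <- function(net) {
  if (net$n_nodes < 2) stop("nodal efficiency needs at least 2 nodes")
  d <- shortest_path_lengths(net)
  inv <- 1 / d
  diag(inv) <- 0
  strength <- numeric(net$n_nodes)
  if (net$K > 0) {
    for (r in seq_len(net$K)) {
      strength[net$edges$i[r]] <- strength[net$edges$i[r]] + net$edges$w[r]
      strength[net$edges$j[r]] <- strength[net$edges$j[r]] + net$edges$w[r]
    }
  }
  data.frame(node = seq_len(net$n_nodes),
             e_nodal = rowSums(inv) / (net$n_nodes - 1),
             strength = strength)
}

#' Induced subgraph on a node subset
#'
#' Keeps edges with both endpoints in \code{nodes}, renumbering nodes to
#' 1..length(nodes) in the given order.
#'
#' @param net \code{weighted_network}; @param nodes integer vector.
#' @return \code{weighted_network}.
#' @export
induced_subnetwork <- function(net, nodes) {
  nodes <- as.integer(nodes)
  map <- integer(net$n_nodes)
  map[nodes] <- seq_along(nodes)
  e <- net$edges
  keep <- map[e$i] > 0 & map[e$j] > 0
  weighted_network(length(nodes),
                   data.frame(i = map[e$i[keep]], j = map[e$j[keep]],
                              w = e$w[keep]))
}
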