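#' Degree-preserving rewiring with weight permutation
#'
#' Maslov-Sneppen double-edge swaps (rejecting self-loops and multi-edges)
#' randomize the topology while preserving N, K and every node's degree;
#' about 10 K swap attempts are made by default. The multiset of original
#' weights is then randomly permuted onto the rewired edges, so the weight
#' distribution is preserved exactly but decoupled from topology.
#'
#' @param net \code{weighted_network} with K >= 2.
#' @param n_swaps swap attempts (default \code{10 * net$K}).
#' @return rewired \code{weighted_network}.
#' @export
rewire_preserving_degree <- function(net, n_swaps = 10 * net$K) {
  if (net$K < 2) stop("need at least 2 edges to rewire")
  g <- as_igraph(net)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = n_swaps))
  el <- igraph::as_edgelist(g2, names = FALSE)
  weighted_network(net$n_nodes,
                   data.frame(i = el[, 1], j = el[, 2],
                              w = sample(net$edges$w)))
}

#' Efficiencies normalized by a matched random-network ensemble
#'
#' Divides the real network's global and local efficiency by the mean over
#' \code{n_nulls} degree-preserving random networks (same N, K, degree
#' sequence and weight multiset). A small-world network shows normalized
#' local efficiency above 1 with normalized global efficiency near 1.
#'
#' @param net \code{weighted_network}.
#' @param n_nulls ensemble size (default 100).
#' @param return_ensemble also return the null networks (default FALSE).
#' @return list of class \code{global_metrics}: \code{e_glob}, \code{e_loc},
#'   \code{e_glob_norm}, \code{e_loc_norm}, ensemble means/SDs and
#'   \code{n_nulls}.
#' @export
normalized_efficiencies <- function(net, n_nulls = 100,
                                    return_ensemble = FALSE) {
  stopifnot(n_nulls >= 1)
  e_glob <- global_efficiency(net)
  e_loc <- local_efficiency(net)
  eg <- el <- numeric(n_nulls)
  ens <- if (return_ensemble) vector("list", n_nulls) else NULL
  for (b in seq_len(n_nulls)) {
    null <- rewire_preserving_degree(net)
    eg[b] <- global_efficiency(null)
    el[b] <- local_efficiency(null)
    if (return_ensemble) ens[[b]] <- null
  }
  if (mean(eg) == 0 || mean(el) == 0)
    stop("null-ensemble mean efficiency is zero; cannot normalize")
  structure(list(e_glob = e_glob, e_loc = e_loc,
                 e_glob_norm = e_glob / mean(eg),
                 e_loc_norm = e_loc / mean(el),
                 null_e_glob_mean = mean(eg), null_e_glob_sd = stats::sd(eg),
                 null_e_loc_mean = mean(el), null_e_loc_sd = stats::sd(el),
                 n_nulls = n_nulls, ensemble = ens),
            class = "global_metrics")
}

#' Small-world test on normalized efficiencies
#'
#' TRUE when normalized local efficiency exceeds 1 and normalized global
#' efficiency is within \code{tol} of 1.
#'
#' @param gm \code{global_metrics} (from
#'   \code{\link{normalized_efficiencies}}) or a list with
#'   \code{e_loc_norm}, \code{e_glob_norm}.
#' @param tol half-width of the "approximately 1" band (default 0.25).
#' @return logical.
#' @export
small_world_check <- function(gm, tol = 0.25) {
  stopifnot(!is.null(gm$e_loc_norm), !is.null(gm$e_glob_norm))
  gm$e_loc_norm > 1 && abs(gm$e_glob_norm - 1) <= tol
}
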