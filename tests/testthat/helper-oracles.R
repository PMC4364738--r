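# Independent oracles used across tests. Deliberately naive implementations:
# Floyd-Warshall over inverse-weight lengths plus direct evaluation of the
# efficiency formulas from the distance matrix.

fw_distances <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1 / a, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

oracle_global_efficiency <- function(a) {
  d <- fw_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (nrow(a) * (nrow(a) - 1))
}

oracle_nodal_efficiency <- function(a) {
  d <- fw_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (nrow(a) - 1)
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  tot <- 0
  for (v in seq_len(n)) {
    nb <- which(a[v, ] > 0)
    if (length(nb) < 2) next
    tot <- tot + oracle_global_efficiency(a[nb, nb, drop = FALSE])
  }
  tot / n
}

random_weighted_adjacency <- function(n, density) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  on <- up[stats::runif(length(up)) < density]
  a[on] <- stats::runif(length(on), 0.05, 1)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# sorted degree sequence / weight multiset of a weighted_network
degree_sequence <- function(net) {
  sort(tabulate(c(net$edges$i, net$edges$j), net$n_nodes))
}
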