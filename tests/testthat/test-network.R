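make_cm <- function(r, n_eff = 100L) {
  structure(list(r = r, n_rois = nrow(r), n_effective_timepoints = n_eff),
            class = "connectivity_matrix")
}

test_that("Pearson connectivity matches closed-form cases", {
  t_idx <- 1:60
  x <- sin(2 * pi * t_idx / 60)
  y <- cos(2 * pi * t_idx / 60)
  cm <- pearson_connectivity(cbind(a = x, b = x, c = -x, d = y))
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "c"], -1)
  expect_lt(abs(cm$r["a", "d"]), 1e-10)  # quadrature sinusoids
  expect_equal(cm$n_effective_timepoints, 60L)
  expect_error(pearson_connectivity(cbind(x, c(NA, x[-1]))), "missing")
  expect_warning(pearson_connectivity(cbind(x, rep(1, 60))), "constant")
})

test_that("Bonferroni thresholding keeps significant positive pairs only", {
  expect_equal(bonferroni_edge_threshold(1024), 0.05 / 523776)
  expect_equal(bonferroni_edge_threshold(1024), 9.546e-8, tolerance = 1e-3)

  zero <- make_cm(diag(10))
  expect_equal(threshold_to_weighted_network(zero)$K, 0L)

  r <- diag(3)
  r[1, 2] <- r[2, 1] <- -0.99  # hugely significant but negative
  r[1, 3] <- r[3, 1] <- 0.99
  net <- threshold_to_weighted_network(make_cm(r))
  expect_equal(net$edges[, c("i", "j")],
               data.frame(i = 1L, j = 3L))
  expect_error(threshold_to_weighted_network(make_cm(r, n_eff = 4L)),
               "degrees of freedom")
})

test_that("thresholding is monotone in alpha on fuzzed matrices", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    a <- random_weighted_adjacency(n, 0.7)
    diag(a) <- 1
    cm <- make_cm(a, n_eff = sample(20:200, 1))
    alphas <- sort(runif(3, 0.001, 0.5))
    key <- function(net) paste(net$edges$i, net$edges$j)
    e1 <- key(threshold_to_weighted_network(cm, alphas[1]))
    e2 <- key(threshold_to_weighted_network(cm, alphas[2]))
    e3 <- key(threshold_to_weighted_network(cm, alphas[3]))
    expect_true(all(e1 %in% e2))
    expect_true(all(e2 %in% e3))
  }
})

test_that("Fisher-z averaging behaves as a z-domain mean", {
  r <- matrix(c(1, 0.3, 0.3, 1), 2)
  single <- group_mean_network(list(make_cm(r)))
  expect_equal(single$r, r, tolerance = 1e-12)

  two <- group_mean_network(list(make_cm(r), make_cm(r)))
  expect_equal(two$r[1, 2], 0.3, tolerance = 1e-12)

  ra <- matrix(c(1, 0.2, 0.2, 1), 2)
  rb <- matrix(c(1, 0.6, 0.6, 1), 2)
  avg <- group_mean_network(list(make_cm(ra), make_cm(rb)))
  expect_equal(avg$r[1, 2], tanh((atanh(0.2) + atanh(0.6)) / 2),
               tolerance = 1e-12)
  expect_gt(avg$r[1, 2], 0.4)  # z-averaging != r-averaging

  rc <- matrix(c(1, 1, 1, 1), 2)
  expect_warning(group_mean_network(list(make_cm(rc))), "clipped")
})

test_that("backbone keeps locally dominant edges and the two-scale structure", {
  # star: every leaf keeps its single (dominant) edge
  n <- 8
  star <- matrix(0, n, n)
  star[1, 2:n] <- star[2:n, 1] <- runif(n - 1, 0.5, 0.9)
  bb <- extract_backbone(make_cm(star))
  expect_equal(bb$K, n - 1L)

  # planted two-scale graph: two 5-cliques (0.8) joined through a connector
  # node by weak bridges (0.2), plus weakest noise edges (0.05)
  a <- matrix(0, 11, 11)
  a[1:5, 1:5] <- 0.8
  a[6:10, 6:10] <- 0.8
  a[5, 11] <- a[11, 5] <- 0.2   # bridges via connector node 11
  a[6, 11] <- a[11, 6] <- 0.2
  noise_pairs <- rbind(c(1, 7), c(2, 9), c(3, 10))
  for (k in seq_len(nrow(noise_pairs))) {
    i <- noise_pairs[k, 1]; j <- noise_pairs[k, 2]
    a[i, j] <- a[j, i] <- 0.05
  }
  diag(a) <- 0
  bb2 <- extract_backbone(make_cm(a), local_alpha = 0.05)
  kept <- paste(bb2$edges$i, bb2$edges$j)
  expect_true(all(c("5 11", "6 11") %in% kept))  # bridges retained
  for (k in seq_len(nrow(noise_pairs)))
    expect_false(paste(noise_pairs[k, 1], noise_pairs[k, 2]) %in% kept)
  # all intra-clique edges retained (rank-1 ties)
  for (cl in list(1:5, 6:10)) {
    pr <- t(combn(cl, 2))
    expect_true(all(paste(pr[, 1], pr[, 2]) %in% kept))
  }
  # rule consistency: kept set equals exhaustive evaluation of the rank rule
  deg <- rowSums(a > 0)
  up <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  manual <- apply(up, 1, function(pr) {
    i <- pr[1]; j <- pr[2]
    ri <- rank(-a[i, a[i, ] > 0], ties.method = "min")[
      which(which(a[i, ] > 0) == j)]
    rj <- rank(-a[j, a[j, ] > 0], ties.method = "min")[
      which(which(a[j, ] > 0) == i)]
    ri == 1 || rj == 1 || ri / deg[i] <= 0.05 || rj / deg[j] <= 0.05
  })
  expect_setequal(kept, paste(up[manual, 1], up[manual, 2]))

  expect_error(extract_backbone(make_cm(matrix(-1, 3, 3))), "positive")
})

test_that("seed-based map equals the seed row of the full correlation matrix", {
  set.seed(23)
  ts <- matrix(rnorm(50 * 8), 50, 8)
  cm <- pearson_connectivity(ts)
  map <- seed_connectivity_map(ts, 3)
  expect_equal(map, unname(cm$r[3, ]), tolerance = 1e-12)
  expect_equal(map[3], 1)
  expect_error(seed_connectivity_map(cbind(ts, 0), 9), "constant")
})

test_that("edge lists round-trip bytewise through the TSV writer", {
  set.seed(29)
  a <- random_weighted_adjacency(12, 0.4)
  net <- network_from_matrix(a)
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_edge_list(net, f1)
  back <- read_edge_list(f1)
  write_edge_list(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(back$n_nodes, net$n_nodes)
  expect_equal(back$edges[, c("i", "j")], net$edges[, c("i", "j")])

  empty <- weighted_network(4, data.frame(i = integer(), j = integer(),
                                          w = numeric()))
  write_edge_list(empty, f1)
  expect_equal(read_edge_list(f1)$K, 0L)
})

test_that("weighted_network validates its invariants", {
  expect_error(weighted_network(3, data.frame(i = 1, j = 1, w = 0.5)),
               "self-loops")
  expect_error(weighted_network(3, data.frame(i = 1, j = 2, w = 0)),
               "positive")
  expect_error(weighted_network(3, data.frame(i = c(1, 2), j = c(2, 1),
                                              w = c(0.5, 0.6))),
               "duplicate")
  expect_error(weighted_network(3, data.frame(i = 1, j = 4, w = 0.5)),
               "exceeds")
})
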