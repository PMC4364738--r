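test_that("permutation test matches the exhaustive enumeration oracle", {
  set.seed(101)
  res <- permutation_test(c(10, 10), c(0, 0), n_perm = 6000)
  expect_equal(res$observed_diff, 10)
  # full enumeration: 6 equiprobable splits, 1 with null diff >= 10;
  # add-one sampling estimate converges to (B/6 + 1)/(B + 1) ~ 1/6
  expect_equal(res$p, 1 / 6, tolerance = 0.12)
  expect_gt(res$p, 0)

  tied <- suppressWarnings(
    permutation_test(rep(3, 5), rep(3, 4), n_perm = 50))
  expect_equal(tied$observed_diff, 0)
  expect_equal(tied$p, 1)
})

test_that("covariate residualization removes a covariate-driven difference", {
  set.seed(103)
  z <- c(rnorm(20, 2), rnorm(20, -2))     # covariate differs by group
  v <- 3 * z + rnorm(40, sd = 0.2)        # values driven only by covariate
  raw <- permutation_test(v[1:20], v[21:40], n_perm = 500)
  adj <- permutation_test(v[1:20], v[21:40], n_perm = 500,
                          covariates = cbind(z))
  expect_lt(raw$p, 0.05)
  expect_gt(adj$p, 0.2)
})

test_that("Benjamini-Hochberg mask matches the hand-executed step-up rule", {
  expect_true(all(fdr_bh(rep(0.001, 100), 0.05)))
  expect_false(any(fdr_bh(rep(0.9, 10), 0.05)))
  expect_identical(fdr_bh(numeric(0)), logical(0))

  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # step-up by hand: largest i with p_(i) <= 0.05 i / 10 is i = 2
  expect_identical(fdr_bh(p, 0.05),
                   c(TRUE, TRUE, rep(FALSE, 8)))
})

test_that("node-wise comparison flags nothing for exchangeable groups", {
  set.seed(107)
  mat_a <- matrix(rnorm(10 * 30), 10, 30)
  mat_b <- matrix(rnorm(12 * 30), 12, 30)
  res <- nodal_comparison(mat_a, mat_b, n_perm = 500)
  expect_length(res$flagged, 0)
})

test_that("node-wise comparison localizes a planted decrease, invariant to node order", {
  set.seed(109)
  n_nodes <- 40
  mat_b <- matrix(rnorm(15 * n_nodes, mean = 5, sd = 0.5), 15, n_nodes)
  mat_a <- matrix(rnorm(12 * n_nodes, mean = 5, sd = 0.5), 12, n_nodes)
  hit <- 1:8
  mat_a[, hit] <- mat_a[, hit] - 2
  res <- nodal_comparison(mat_a, mat_b, n_perm = 1000)
  expect_setequal(res$flagged, hit)

  ord <- sample(n_nodes)
  set.seed(500)
  r1 <- nodal_comparison(mat_a, mat_b, n_perm = 1000)
  set.seed(500)
  r2 <- nodal_comparison(mat_a[, ord], mat_b[, ord], n_perm = 1000)
  expect_setequal(ord[r2$flagged], r1$flagged)
})

test_that("hub-bin profiles partition nodes with percentages summing to 100", {
  grid <- rep(seq(0, 7), each = 16)  # 8 distinct values, 16 nodes each
  prof <- hub_bin_profile(grid, 8)
  expect_equal(prof$percent, rep(12.5, 8))

  expect_warning(flat <- hub_bin_profile(rep(2, 50), 8), "constant")
  expect_equal(flat$percent[1], 100)

  set.seed(113)
  for (rep in 1:200) {
    v <- rnorm(sample(10:200, 1))
    p <- hub_bin_profile(v, 8)
    expect_equal(sum(p$percent), 100, tolerance = 1e-9)
    expect_true(all(p$percent >= 0))
    expect_length(p$percent, 8)
  }
})

test_that("module enrichment agrees with the hypergeometric tail", {
  set.seed(127)
  labels <- rep(1:4, c(20, 15, 15, 10))
  flagged <- c(1:10, 25:28, 40:42)  # concentrated in module 1
  res <- module_enrichment(flagged, labels, n_draws = 4000)
  expect_equal(sum(res$observed), length(flagged))
  k <- length(flagged)
  for (s in 1:4) {
    exact <- phyper(res$observed[s] - 1, res$sizes[s],
                    length(labels) - res$sizes[s], k, lower.tail = FALSE)
    se <- sqrt(exact * (1 - exact) / 4000)
    expect_lt(abs(res$p[s] - exact), 3 * se + 2 / 4000)
  }

  all_flagged <- module_enrichment(seq_along(labels), labels, n_draws = 200)
  expect_equal(all_flagged$p, rep(1, 4))
})

test_that("partial correlation equals residual and recursive-formula routes", {
  set.seed(131)
  n <- 60
  z <- rnorm(n)
  x <- rnorm(n) + z
  y <- 2 * x + 3 * z + rnorm(n)

  plain <- partial_correlation(x, y)
  expect_equal(plain$r, cor(x, y), tolerance = 1e-12)

  expect_warning(dup <- partial_correlation(x, z, cbind(z)), "covariates")
  expect_equal(dup$r, 0)

  pc <- partial_correlation(x, y, cbind(z))
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  recursive <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(pc$r, recursive, tolerance = 1e-10)

  x_na <- x; x_na[1:5] <- NA
  expect_equal(partial_correlation(x_na, y, cbind(z))$n, n - 5)
  expect_error(partial_correlation(x[1:3], y[1:3], cbind(z[1:3], z[1:3]^2)),
               "complete cases")
})

test_that("Payne's calcium correction follows the albumin formula", {
  expect_equal(payne_corrected_calcium(2.20, 40), 2.20)
  expect_equal(payne_corrected_calcium(2.20, 30), 2.40)
  expect_equal(payne_corrected_calcium(2.20, 50), 2.00)
  expect_error(payne_corrected_calcium(2.2, 0), "positive")
})

test_that("demographic tests reproduce the printed cohort-table p-values", {
  # gender counts 16/6 vs 19/10, Pearson chi-square without correction
  cs <- chisq_test_counts(c(16, 6), c(19, 10))
  expect_equal(cs$p, 0.583, tolerance = 0.002)

  # age 38 +/- 10.5 (n=22) vs 42.1 +/- 8.4 (n=29), pooled two-sided t
  tt <- t_test_from_summary(38, 10.5, 22, 42.1, 8.4, 29)
  expect_equal(tt$p, 0.127, tolerance = 0.01)

  same <- chisq_test_counts(c(10, 5), c(20, 10))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
})

test_that("demographics_tests runs a manifest end to end", {
  set.seed(137)
  manifest <- data.frame(
    group = rep(c("patient", "control"), c(12, 14)),
    sex = rbinom(26, 1, 0.6),
    age = c(rnorm(12, 40, 9), rnorm(14, 42, 9)))
  out <- demographics_tests(manifest)
  expect_true(all(c("sex", "age") %in% out$variable))
  expect_true(all(out$p >= 0 & out$p <= 1))
  chk <- t.test(age ~ group, manifest, var.equal = TRUE)
  expect_equal(out$p[out$variable == "age"], chk$p.value, tolerance = 1e-12)
})

test_that("Dice coefficient handles overlap and degenerate sets", {
  expect_equal(dice_coefficient(1:5, 1:5), 1)
  expect_equal(dice_coefficient(1:3, 4:6), 0)
  expect_equal(dice_coefficient(c(1, 2), c(2, 3)), 0.5)
  expect_warning(d <- dice_coefficient(integer(), integer()), "empty")
  expect_equal(d, 1)
})
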