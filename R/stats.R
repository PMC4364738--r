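#' Permutation test for a difference in group means
#'
#' Observed statistic: mean(a) - mean(b). The empirical null reallocates
#' the pooled values into two groups of the original sizes uniformly at
#' random. The 95th percentile point of the null (5th for the "less" tail)
#' is the one-tailed critical value. P-values use the add-one convention
#' \eqn{p = (\#\{null \ge obs\} + 1) / (B + 1)} (never exactly 0). When
#' covariates are supplied, all values are first residualized on them
#' (pooled OLS with intercept) — the head-motion adjustment used for
#' group-level comparisons.
#'
#' @param a,b numeric vectors (both length >= 2).
#' @param n_perm permutations (default 10000; < 100 draws a warning).
#' @param tail \code{"greater"} (a > b) or \code{"less"}.
#' @param covariates optional matrix/data.frame with
#'   \code{length(a) + length(b)} rows, ordered as \code{c(a, b)}.
#' @return list of class \code{permutation_result}: \code{observed_diff},
#'   \code{null_diffs}, \code{critical_value}, \code{p}.
#' @export
permutation_test <- function(a, b, n_perm = 10000L,
                             tail = c("greater", "less"),
                             covariates = NULL) {
  tail <- match.arg(tail)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (n_perm < 100) warning("fewer than 100 permutations; p is unstable")
  v <- c(a, b)
  if (!is.null(covariates)) {
    z <- cbind(1, as.matrix(covariates))
    if (nrow(z) != length(v)) stop("covariate rows must match length(a)+length(b)")
    v <- as.numeric(stats::lm.fit(z, v)$residuals)
  }
  n_a <- length(a)
  n <- length(v)
  observed <- mean(v[seq_len(n_a)]) - mean(v[-seq_len(n_a)])
  sum_all <- sum(v)
  null_diffs <- vapply(seq_len(n_perm), function(p) {
    sa <- sum(v[sample.int(n, n_a)])
    sa / n_a - (sum_all - sa) / (n - n_a)
  }, 0)
  if (tail == "greater") {
    p <- (sum(null_diffs >= observed) + 1) / (n_perm + 1)
    crit <- stats::quantile(null_diffs, 0.95, names = FALSE)
  } else {
    p <- (sum(null_diffs <= observed) + 1) / (n_perm + 1)
    crit <- stats::quantile(null_diffs, 0.05, names = FALSE)
  }
  structure(list(observed_diff = observed, null_diffs = null_diffs,
                 critical_value = crit, p = p, tail = tail,
                 n_perm = n_perm),
            class = "permutation_result")
}

#' Benjamini-Hochberg step-up rejection mask
#'
#' @param p_values numeric vector in [0, 1].
#' @param q FDR level (default 0.05).
#' @return logical mask of rejections (empty input gives an empty mask).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Node-wise group comparison with FDR control
#'
#' Per-node permutation test for decreased values in group A relative to
#' group B (tail "less"), followed by Benjamini-Hochberg over all nodes.
#' All nodes share one set of label permutations, computed by matrix
#' products for speed.
#'
#' @param mat_a,mat_b subjects x nodes matrices (same node columns).
#' @param n_perm permutations (default 10000).
#' @param q FDR level (default 0.05).
#' @param tail direction for group A relative to B (default "less":
#'   decreases in A).
#' @return list: \code{flagged} (node indices), \code{p} (raw per-node),
#'   \code{rejected} mask, \code{observed_diff} per node.
#' @export
nodal_comparison <- function(mat_a, mat_b, n_perm = 10000L, q = 0.05,
                             tail = c("less", "greater")) {
  tail <- match.arg(tail)
  mat_a <- as.matrix(mat_a); mat_b <- as.matrix(mat_b)
  if (ncol(mat_a) != ncol(mat_b)) stop("node sets differ")
  v <- rbind(mat_a, mat_b)
  n <- nrow(v); n_a <- nrow(mat_a)
  observed <- colMeans(mat_a) - colMeans(mat_b)
  col_sums <- colSums(v)
  count <- integer(ncol(v))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, n_a)
    sa <- colSums(v[idx, , drop = FALSE])
    diff_b <- sa / n_a - (col_sums - sa) / (n - n_a)
    count <- count + if (tail == "less") (diff_b <= observed) else
      (diff_b >= observed)
  }
  p <- (count + 1) / (n_perm + 1)
  rejected <- fdr_bh(p, q)
  list(flagged = which(rejected), p = p, rejected = rejected,
       observed_diff = observed)
}

#' Per-subject hub-bin profile
#'
#' Divides the nodes into \code{n_bins} equally spaced bins between the
#' subject's minimum and maximum of the binning statistic (nodal efficiency
#' by default; nodal strength is the common alternative). The first bin
#' holds peripheral nodes, the last bin hubs; the top bin is right-closed.
#' Constant input puts all nodes in bin 1 with a warning.
#'
#' @param values numeric vector (one subject's per-node statistic).
#' @param n_bins number of bins (default 8).
#' @return list: \code{percent} (length \code{n_bins}, sums to 100),
#'   \code{counts}, \code{edges} (length \code{n_bins + 1}).
#' @export
hub_bin_profile <- function(values, n_bins = 8L) {
  stopifnot(length(values) >= 1, n_bins >= 1)
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    warning("constant values: all nodes assigned to bin 1")
    counts <- c(length(values), rep(0L, n_bins - 1))
    edges <- seq(lo, lo + 1, length.out = n_bins + 1)
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1)
    bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE),
                     1L), n_bins)
    counts <- tabulate(bin, n_bins)
  }
  list(percent = 100 * counts / length(values), counts = counts,
       edges = edges)
}

#' Module enrichment of a flagged node set by resampling
#'
#' Draws |flagged| nodes uniformly without replacement \code{n_draws} times
#' and records the per-module counts, giving an empirical null for the
#' observed distribution of flagged nodes over modules. Per module,
#' \eqn{p = (\#\{draws \ge observed\} + 1) / (n_{draws} + 1)}. The exact
#' reference is the hypergeometric tail, which the empirical p approaches.
#'
#' @param flagged integer node indices.
#' @param labels module label per node.
#' @param n_draws resampling draws (default 10000).
#' @return list: \code{observed}, \code{expected}, \code{p} (per module),
#'   \code{n_draws}.
#' @export
module_enrichment <- function(flagged, labels, n_draws = 10000L) {
  labels <- as.integer(factor(labels))
  n <- length(labels)
  flagged <- unique(as.integer(flagged))
  if (any(flagged < 1 | flagged > n)) stop("flagged nodes outside node set")
  k <- length(flagged)
  n_mod <- max(labels)
  observed <- tabulate(labels[flagged], n_mod)
  sizes <- tabulate(labels, n_mod)
  count_ge <- integer(n_mod)
  for (b in seq_len(n_draws)) {
    draw <- tabulate(labels[sample.int(n, k)], n_mod)
    count_ge <- count_ge + (draw >= observed)
  }
  list(observed = observed, expected = k * sizes / n,
       p = (count_ge + 1) / (n_draws + 1), n_draws = n_draws,
       sizes = sizes)
}

#' Partial correlation with significance
#'
#' Pearson correlation of the OLS residuals of x and y on an intercept plus
#' the covariates, over complete cases; p from the t distribution with
#' df = n - n_covariates - 2.
#'
#' @param x,y numeric vectors.
#' @param covariates optional matrix/data.frame.
#' @return list: \code{r}, \code{p}, \code{n}, \code{df}.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n_cov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  cc <- stats::complete.cases(x, y,
                              if (is.null(covariates)) rep(TRUE, length(x))
                              else as.matrix(covariates))
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  df <- n - n_cov - 2
  if (df <= 0) stop("not enough complete cases for the covariate set")
  if (n_cov > 0) {
    z <- cbind(1, as.matrix(covariates)[cc, , drop = FALSE])
    x <- stats::lm.fit(z, x)$residuals
    y <- stats::lm.fit(z, y)$residuals
  }
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    warning("a variable is fully explained by the covariates; r set to 0")
    return(list(r = 0, p = 1, n = n, df = df))
  }
  r <- stats::cor(x, y)
  t <- abs(r) * sqrt(df / max(1 - r^2, .Machine$double.xmin))
  list(r = r, p = 2 * stats::pt(t, df, lower.tail = FALSE), n = n, df = df)
}

#' Albumin-corrected serum calcium (Payne's formula)
#'
#' corrected = measured + 0.02 x (40 - albumin), calcium in mmol/L and
#' albumin in g/L.
#'
#' @param ca_measured measured calcium (mmol/L).
#' @param albumin serum albumin (g/L), > 0.
#' @return corrected calcium (mmol/L).
#' @export
payne_corrected_calcium <- function(ca_measured, albumin) {
  if (any(albumin <= 0)) stop("albumin must be positive")
  ca_measured + 0.02 * (40 - albumin)
}

#' Two-sample pooled t test from printed summary statistics
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return list: \code{t}, \code{df}, \code{p} (two-sided).
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Chi-square test on two-group category counts
#'
#' Pearson chi-square without continuity correction, e.g. on male/female
#' counts per group.
#'
#' @param counts1,counts2 integer count vectors (same categories).
#' @return list: \code{statistic}, \code{df}, \code{p}.
#' @export
chisq_test_counts <- function(counts1, counts2) {
  tab <- rbind(counts1, counts2)
  if (any(colSums(tab) == 0)) warning("category with zero total count")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Demographic comparison table for a subject manifest
#'
#' Chi-square (no continuity correction) on the sex composition and pooled
#' two-sided t tests on continuous covariates, patient vs control.
#'
#' @param manifest data.frame with a \code{group} column
#'   (patient/control), a binary \code{sex} column, and continuous columns.
#' @param continuous names of continuous columns to test (default: all
#'   numeric except sex).
#' @return data.frame: variable, test, statistic, p.
#' @export
demographics_tests <- function(manifest, continuous = NULL) {
  stopifnot(all(c("group", "sex") %in% names(manifest)))
  groups <- unique(manifest$group)
  if (length(groups) != 2) stop("exactly two groups required")
  a <- manifest[manifest$group == groups[1], ]
  b <- manifest[manifest$group == groups[2], ]
  if (is.null(continuous)) {
    num <- vapply(manifest, is.numeric, TRUE)
    continuous <- setdiff(names(manifest)[num], "sex")
  }
  cs <- chisq_test_counts(tabulate(factor(a$sex, levels = sort(unique(manifest$sex)))),
                          tabulate(factor(b$sex, levels = sort(unique(manifest$sex)))))
  rows <- data.frame(variable = "sex", test = "chi-square",
                     statistic = cs$statistic, p = cs$p,
                     stringsAsFactors = FALSE)
  for (v in continuous) {
    xa <- a[[v]][!is.na(a[[v]])]
    xb <- b[[v]][!is.na(b[[v]])]
    if (length(xa) < 2 || length(xb) < 2) next
    tt <- stats::t.test(xa, xb, var.equal = TRUE)
    rows <- rbind(rows, data.frame(variable = v, test = "pooled t",
                                   statistic = unname(tt$statistic),
                                   p = tt$p.value, stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  rows
}

#' Dice coefficient of two node sets
#'
#' 2|A n B| / (|A| + |B|); two empty sets give 1 with a warning.
#'
#' @param set_a,set_b vectors of node identifiers.
#' @return scalar in [0, 1].
#' @export
dice_coefficient <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0 && length(set_b) == 0) {
    warning("both sets empty; Dice defined as 1")
    return(1)
  }
  2 * length(intersect(set_a, set_b)) / (length(set_a) + length(set_b))
}
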