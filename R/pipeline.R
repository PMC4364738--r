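#' Default pipeline configuration
#'
#' Collects every tunable of the group pipeline in one serializable list.
#' The defaults reproduce the primary analysis: 5 discarded volumes,
#' 0.01-0.1 Hz band, 24-parameter motion regression without global-signal
#' removal, Bonferroni edge threshold at family level 0.05, 100-network
#' null ensembles, 10,000 permutations/draws, 8 hub bins, reference
#' partition from the control group.
#'
#' @param spec \code{\link{cohort_spec}} used when \code{synthetic = TRUE}.
#' @param n_discard,low_hz,high_hz,motion_24,global_signal preprocessing.
#' @param alpha Bonferroni family level for edge retention.
#' @param edge_df \code{"band_corrected"} (default) tests edge significance
#'   with \code{\link{effective_df}} — the honest df after band-pass
#'   filtering; \code{"nominal"} uses retained volumes minus 2.
#' @param backbone_alpha node-local level for backbone sparsification.
#' @param n_nulls random networks per null ensemble (0 disables
#'   normalization and module-level normalized metrics).
#' @param n_perm permutations for group tests.
#' @param n_draws draws for module-enrichment resampling.
#' @param n_bins hub-profile bins.
#' @param bin_statistic \code{"e_nodal"} or \code{"strength"}.
#' @param seed master seed for the statistical stage.
#' @return named list of class \code{run_config}.
#' @export
default_config <- function(spec = cohort_spec(), n_discard = 5L,
                           low_hz = 0.01, high_hz = 0.1, motion_24 = TRUE,
                           global_signal = FALSE, alpha = 0.05,
                           edge_df = c("band_corrected", "nominal"),
                           backbone_alpha = 0.05, n_nulls = 100L,
                           n_perm = 10000L, n_draws = 10000L, n_bins = 8L,
                           bin_statistic = c("e_nodal", "strength"),
                           seed = 1L) {
  structure(list(spec = spec, n_discard = n_discard, low_hz = low_hz,
                 high_hz = high_hz, motion_24 = motion_24,
                 global_signal = global_signal, alpha = alpha,
                 edge_df = match.arg(edge_df),
                 backbone_alpha = backbone_alpha, n_nulls = n_nulls,
                 n_perm = n_perm, n_draws = n_draws, n_bins = n_bins,
                 bin_statistic = match.arg(bin_statistic),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full group analysis
#'
#' Stages: (1) preprocess every subject (discard/detrend, band-pass,
#' nuisance regression); (2) individual Pearson connectivity and
#' Bonferroni thresholding into sparse positive weighted networks; (3)
#' group-mean (Fisher-z) matrix of the control group, backbone extraction
#' and spectral module detection — the reference partition; (4) per-subject
#' global/nodal metrics, optionally normalized by degree-preserving null
#' ensembles; (5) statistics: permutation tests on global metrics
#' (head-motion summaries as covariates), module-connectivity comparison
#' with BH correction, node-wise comparison with FDR + module enrichment,
#' hub-bin profiles, and partial correlations of efficiency with
#' hemoglobin in the patient group (controlling age, sex, mean FD).
#'
#' @param cohort a cohort (from \code{\link{generate_cohort}} or assembled
#'   from disk); \code{NULL} generates one from \code{config$spec}.
#' @param config a \code{\link{default_config}} list.
#' @return a report bundle (list) with elements \code{config},
#'   \code{partition}, \code{global}, \code{nodal}, \code{module_conn},
#'   \code{stats}.
#' @export
run_group_pipeline <- function(cohort = NULL, config = default_config()) {
  if (is.null(cohort)) cohort <- generate_cohort(config$spec)
  spec <- cohort$spec
  set.seed(config$seed)

  message("stage 1/5: preprocessing")
  prep <- lapply(cohort$subjects, function(s) {
    out <- tryCatch(
      preprocess_subject(s, tr_seconds = spec$tr_seconds,
                         n_discard = config$n_discard,
                         low_hz = config$low_hz, high_hz = config$high_hz,
                         motion_24 = config$motion_24,
                         global_signal = config$global_signal),
      error = function(e) stop(sprintf("preprocessing failed for %s: %s",
                                       s$subject_id, conditionMessage(e))))
    out
  })
  groups <- vapply(cohort$subjects, function(s) s$group, "")
  is_pat <- groups == "patient"

  message("stage 2/5: individual networks")
  cms <- lapply(prep, function(p) pearson_connectivity(p$timeseries))
  df_over <- if (identical(config$edge_df, "nominal")) NULL else
    effective_df(nrow(prep[[1]]$timeseries), spec$tr_seconds,
                 config$low_hz, config$high_hz)
  nets <- lapply(cms, function(cm)
    threshold_to_weighted_network(cm, alpha = config$alpha,
                                  df_override = df_over))

  message("stage 3/5: backbone and reference partition (controls)")
  group_cm <- group_mean_network(cms[!is_pat])
  backbone <- extract_backbone(group_cm, local_alpha = config$backbone_alpha)
  partition <- spectral_partition(backbone)

  message("stage 4/5: metrics")
  glob <- vector("list", length(nets))
  nodal <- vector("list", length(nets))
  for (i in seq_along(nets)) {
    if (config$n_nulls > 0 && nets[[i]]$K >= 2) {
      gm <- normalized_efficiencies(nets[[i]], config$n_nulls)
    } else {
      gm <- list(e_glob = global_efficiency(nets[[i]]),
                 e_loc = local_efficiency(nets[[i]]),
                 e_glob_norm = NA_real_, e_loc_norm = NA_real_)
    }
    ms <- prep[[i]]$motion_summary
    glob[[i]] <- data.frame(
      subject_id = cohort$subjects[[i]]$subject_id, group = groups[i],
      e_glob = gm$e_glob, e_loc = gm$e_loc,
      e_glob_norm = gm$e_glob_norm, e_loc_norm = gm$e_loc_norm,
      k_edges = nets[[i]]$K, mean_fd = ms$mean_fd, max_fd = ms$max_fd,
      rms_fd = ms$rms_fd, stringsAsFactors = FALSE)
    nodal[[i]] <- nodal_efficiency(nets[[i]])
  }
  glob <- do.call(rbind, glob)
  nodal_mat <- t(vapply(nodal, function(x) x$e_nodal,
                        numeric(spec$n_rois)))
  strength_mat <- t(vapply(nodal, function(x) x$strength,
                           numeric(spec$n_rois)))

  message("stage 5/5: statistics")
  fd_cov <- cbind(glob$mean_fd, glob$max_fd, glob$rms_fd)
  perm_global <- list()
  for (metric in c("e_glob", "e_loc")) {
    perm_global[[metric]] <- permutation_test(
      glob[[metric]][is_pat], glob[[metric]][!is_pat],
      n_perm = config$n_perm, tail = "less",
      covariates = rbind(fd_cov[is_pat, , drop = FALSE],
                         fd_cov[!is_pat, , drop = FALSE]))
  }
  if (config$n_nulls > 0) {
    perm_global$e_loc_norm <- permutation_test(
      glob$e_loc_norm[is_pat], glob$e_loc_norm[!is_pat],
      n_perm = config$n_perm, tail = "greater",
      covariates = rbind(fd_cov[is_pat, , drop = FALSE],
                         fd_cov[!is_pat, , drop = FALSE]))
    perm_global$e_glob_norm <- permutation_test(
      glob$e_glob_norm[is_pat], glob$e_glob_norm[!is_pat],
      n_perm = config$n_perm, tail = "less",
      covariates = rbind(fd_cov[is_pat, , drop = FALSE],
                         fd_cov[!is_pat, , drop = FALSE]))
  }

  mc <- module_connectivity(nets, partition)
  mc_p <- vapply(names(mc), function(col)
    permutation_test(mc[[col]][is_pat], mc[[col]][!is_pat],
                     n_perm = config$n_perm, tail = "less")$p, 0)
  mc_rejected <- fdr_bh(mc_p, 0.05)

  nodal_cmp <- nodal_comparison(nodal_mat[is_pat, , drop = FALSE],
                                nodal_mat[!is_pat, , drop = FALSE],
                                n_perm = config$n_perm)
  enrich <- module_enrichment(nodal_cmp$flagged, partition$labels,
                              n_draws = config$n_draws)

  bin_src <- if (config$bin_statistic == "strength") strength_mat else
    nodal_mat
  bins <- t(apply(bin_src, 1, function(v)
    hub_bin_profile(v, config$n_bins)$percent))
  bin_p <- vapply(seq_len(config$n_bins), function(b)
    permutation_test(bins[is_pat, b], bins[!is_pat, b],
                     n_perm = config$n_perm, tail = "less")$p, 0)

  clin <- generate_clinical_table(cohort)
  pat_clin <- clin[is_pat, ]
  cov_mat <- cbind(pat_clin$age, pat_clin$sex, glob$mean_fd[is_pat])
  max_cov <- max(sum(is_pat) - 4, 0)  # keep df = n - n_cov - 2 >= 2
  if (ncol(cov_mat) > max_cov) {
    warning("patient group too small for the full covariate set; trimming")
    cov_mat <- cov_mat[, seq_len(max_cov), drop = FALSE]
    if (max_cov == 0) cov_mat <- NULL
  }
  hb_cor <- list(
    e_glob = partial_correlation(glob$e_glob[is_pat], pat_clin$hemoglobin,
                                 cov_mat),
    e_loc = partial_correlation(glob$e_loc[is_pat], pat_clin$hemoglobin,
                                cov_mat))

  list(config = config, partition = partition, backbone = backbone,
       global = glob,
       nodal = list(e_nodal = nodal_mat, strength = strength_mat),
       module_conn = list(values = mc, p = mc_p, rejected = mc_rejected),
       stats = list(global_tests = perm_global, nodal = nodal_cmp,
                    enrichment = enrich,
                    hub_bins = list(percent = bins, p = bin_p),
                    hemoglobin = hb_cor),
       groups = groups, ground_truth = cohort$ground_truth)
}
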