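test_that("cohort generation is deterministic in the seed", {
  spec <- cohort_spec(n_patients = 2, n_controls = 2, n_rois = 16,
                      module_sizes = c(8L, 8L), n_volumes = 40, seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$subjects[[1]]$timeseries, c2$subjects[[1]]$timeseries)
  expect_identical(c1$subjects[[3]]$motion, c2$subjects[[3]]$motion)
  expect_identical(generate_clinical_table(c1), generate_clinical_table(c2))

  spec2 <- cohort_spec(n_patients = 2, n_controls = 2, n_rois = 16,
                       module_sizes = c(8L, 8L), n_volumes = 40, seed = 43)
  c3 <- generate_cohort(spec2)
  expect_false(identical(c1$subjects[[1]]$timeseries,
                         c3$subjects[[1]]$timeseries))
  expect_identical(c1$ground_truth$planted_partition,
                   c3$ground_truth$planted_partition)
})

test_that("noise-free single-factor spec gives perfectly correlated ROIs", {
  spec <- cohort_spec(n_patients = 1, n_controls = 1, n_rois = 6,
                      module_sizes = 6L, n_volumes = 64,
                      intra_loading = 0.7, inter_loading = 0,
                      noise_sd = 0, seed = 5)
  set.seed(5)
  rec <- generate_subject_timeseries(spec, "control")
  r <- cor(rec$timeseries)
  expect_true(all(abs(r[upper.tri(r)] - 1) < 1e-8))
})

test_that("pure-noise spec gives near-zero correlations", {
  spec <- cohort_spec(n_patients = 1, n_controls = 1, n_rois = 12,
                      module_sizes = 12L, n_volumes = 400,
                      intra_loading = 0, inter_loading = 0,
                      noise_sd = 1, seed = 7)
  set.seed(7)
  rec <- generate_subject_timeseries(spec, "control")
  r <- cor(rec$timeseries)
  expect_lt(mean(abs(r[upper.tri(r)])), 3 / sqrt(spec$n_volumes))
})

test_that("long-run within-module correlation matches the factor-model closed form", {
  # intra 0.7, inter 0.2, noise 0.5: within r = (0.49+0.04)/0.78,
  # between r = 0.04/0.78 (global factor contributes to both)
  spec <- cohort_spec(n_patients = 1, n_controls = 1, n_rois = 20,
                      module_sizes = c(10L, 10L), n_volumes = 10000,
                      intra_loading = 0.7, inter_loading = 0.2,
                      noise_sd = 0.5, seed = 11)
  set.seed(11)
  rec <- generate_subject_timeseries(spec, "control")
  r <- cor(rec$timeseries)
  labels <- rep(1:2, each = 10)
  same <- outer(labels, labels, "==") & upper.tri(r)
  diff <- (!outer(labels, labels, "==")) & upper.tri(r)
  expect_equal(mean(r[same]), 0.53 / 0.78, tolerance = 0.03)
  # between-module r inherits the realized factor-factor sample correlation,
  # so the band is absolute and wider
  expect_lt(abs(mean(r[diff]) - 0.04 / 0.78), 0.02)
})

test_that("patient effect lowers within-affected-module correlation", {
  spec <- cohort_spec(n_patients = 1, n_controls = 1, n_rois = 24,
                      module_sizes = c(12L, 12L), n_volumes = 4000,
                      patient_effect = 0.5, covariate_coupling = 0, seed = 13)
  set.seed(13)
  pat <- generate_subject_timeseries(spec, "patient", affected_module = 1)
  ctl <- generate_subject_timeseries(spec, "control", affected_module = 1)
  in_mod <- function(ts) {
    r <- cor(ts)[1:12, 1:12]
    mean(r[upper.tri(r)])
  }
  expect_lt(in_mod(pat$timeseries), in_mod(ctl$timeseries))
})

test_that("generated series are band-limited after the band-pass stage", {
  spec <- cohort_spec(n_patients = 1, n_controls = 1, n_rois = 8,
                      module_sizes = 8L, n_volumes = 160, seed = 3)
  set.seed(3)
  rec <- generate_subject_timeseries(spec, "control")
  bp <- bandpass_filter(rec$timeseries, spec$tr_seconds)
  f <- abs(seq(0, 159) / (160 * 3))
  f <- pmin(f, 1 / 3 - f)  # fold to [0, Nyquist]
  for (j in c(1, 5)) {
    pw <- Mod(fft(bp[, j]))^2
    in_band <- f >= 0.0099 & f <= 0.1001
    expect_gt(sum(pw[in_band]) / sum(pw), 0.9)
  }
})

test_that("clinical table has one row per subject and controllable missingness", {
  spec <- cohort_spec(n_patients = 8, n_controls = 7, n_rois = 8,
                      module_sizes = 8L, n_volumes = 40, seed = 21)
  co <- generate_cohort(spec)
  tab <- generate_clinical_table(co)
  expect_equal(nrow(tab), 15)
  expect_false(anyNA(tab$hemoglobin))
  tab6 <- generate_clinical_table(co, n_missing_hemoglobin = 6)
  expect_equal(sum(is.na(tab6$hemoglobin)), 6)
  expect_true(all(tab6$group[is.na(tab6$hemoglobin)] == "patient"))
  expect_error(generate_clinical_table(co, n_missing_hemoglobin = 9),
               "more missing")
})

test_that("spec validation rejects inconsistent designs", {
  expect_error(cohort_spec(module_sizes = c(10L, 10L)), "sum to n_rois")
  expect_error(cohort_spec(n_rois = 16L, module_sizes = c(8L, 8L),
                           intra_loading = 0.2, inter_loading = 0.5),
               "inter_loading")
  expect_error(cohort_spec(n_rois = 16L, module_sizes = c(8L, 8L),
                           patient_effect = 0), "patient_effect")
  spec <- cohort_spec(n_rois = 16L, module_sizes = c(8L, 8L))
  expect_error(generate_subject_timeseries(spec, "control",
                                           loading_scale = 2),
               "intra loading")
})

test_that("planted partition is the modularity optimum of the population matrix", {
  skip_if_not_installed("mclust")
  spec <- cohort_spec()
  pop <- population_correlation(spec)
  diag(pop) <- 0
  part <- spectral_partition(network_from_matrix(pop))
  expect_equal(part$n_modules, 4L)
  planted <- rep(seq_along(spec$module_sizes), spec$module_sizes)
  expect_equal(mclust::adjustedRandIndex(part$labels, planted), 1)
})
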