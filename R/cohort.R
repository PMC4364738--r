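#' Specification of a synthetic two-group cohort
#'
#' Defines the design of a simulated resting-state cohort: two groups of
#' subjects, each with an ROI-by-time matrix generated from a modular factor
#' model. Every ROI signal is a weighted sum of its module's latent factor, a
#' global factor shared by all ROIs, and independent noise; all factors are
#' band-limited (0.01-0.1 Hz) unit-variance series, so the planted
#' correlation structure survives band-pass filtering. In the patient group
#' the intra-module loading of one designated module (the largest) is
#' multiplied by \code{patient_effect}, weakening its internal connectivity.
#' A simulated hemoglobin value scales each subject's intra-module loadings
#' through \code{covariate_coupling}, planting a recoverable
#' efficiency-hemoglobin association.
#'
#' Under this model the population correlation between two ROIs of the same
#' module is \eqn{(a^2 + b^2) / (a^2 + b^2 + \sigma^2)} and between modules
#' \eqn{b^2 / (a^2 + b^2 + \sigma^2)}, where \eqn{a} is the intra-module
#' loading, \eqn{b} the global loading and \eqn{\sigma} the noise SD.
#' Positive definiteness is automatic at any dimension.
#'
#' @param n_patients,n_controls group sizes (defaults 22 and 29).
#' @param n_rois number of regions; must equal \code{sum(module_sizes)}.
#' @param n_volumes scan length in volumes (default 160, of which the first
#'   five are discarded downstream).
#' @param tr_seconds repetition time in seconds (default 3).
#' @param module_sizes sizes of the planted modules (default 40/31/36/21, a
#'   128-ROI scale-down of a four-module cortical parcellation).
#' @param intra_loading,inter_loading factor loadings, \code{0 <=
#'   inter_loading < intra_loading < 1}.
#' @param patient_effect multiplicative reduction in (0, 1] applied to the
#'   affected module's intra loading for patients.
#' @param covariate_coupling slope tying the z-scored hemoglobin value to the
#'   subject's intra-module loading scale (0 = no coupling).
#' @param noise_sd SD of the independent noise term.
#' @param motion_step_sd per-volume SD of the motion random walk
#'   (mm for translations, degrees for rotations).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 22L, n_controls = 29L,
                        n_rois = 128L, n_volumes = 160L, tr_seconds = 3,
                        module_sizes = c(40L, 31L, 36L, 21L),
                        intra_loading = 0.65, inter_loading = 0.07,
                        patient_effect = 0.6, covariate_coupling = 0.1,
                        noise_sd = 0.7, motion_step_sd = 0.02, seed = 1L) {
  stopifnot(n_patients >= 1, n_controls >= 1, n_volumes >= 20,
            tr_seconds > 0, noise_sd >= 0, motion_step_sd >= 0)
  if (sum(module_sizes) != n_rois)
    stop("module_sizes must sum to n_rois")
  ok_loadings <- inter_loading >= 0 && intra_loading < 1 &&
    (inter_loading < intra_loading ||
       (intra_loading == 0 && inter_loading == 0))  # pure-noise spec allowed
  if (!ok_loadings)
    stop("require 0 <= inter_loading < intra_loading < 1 (or both zero)")
  if (!(patient_effect > 0 && patient_effect <= 1))
    stop("patient_effect must lie in (0, 1]")
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_rois = as.integer(n_rois), n_volumes = as.integer(n_volumes),
    tr_seconds = tr_seconds, module_sizes = as.integer(module_sizes),
    intra_loading = intra_loading, inter_loading = inter_loading,
    patient_effect = patient_effect, covariate_coupling = covariate_coupling,
    noise_sd = noise_sd, motion_step_sd = motion_step_sd,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Band-limited unit-variance series
#'
#' White Gaussian noise masked in the frequency domain to \code{[low_hz,
#' high_hz]} and rescaled to unit variance. Masking (rather than a recursive
#' filter) gives exact band control with no transients.
#'
#' @param n series length; @param tr_seconds sampling interval.
#' @param low_hz,high_hz pass band in Hz.
#' @return numeric vector of length \code{n} with mean 0, SD 1.
#' @keywords internal
band_limited_series <- function(n, tr_seconds, low_hz = 0.01, high_hz = 0.1) {
  x <- stats::rnorm(n)
  f <- frequency_grid(n, tr_seconds)
  xf <- stats::fft(x)
  xf[f < low_hz | f > high_hz] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s < .Machine$double.eps) stop("degenerate band: no frequency bins kept")
  (y - mean(y)) / s
}

# |frequency| in Hz associated with each DFT bin
frequency_grid <- function(n, tr_seconds) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  abs(k) / (n * tr_seconds)
}

#' Simulate one subject's ROI time series and motion table
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param group \code{"patient"} or \code{"control"}.
#' @param subject_id identifier string.
#' @param loading_scale multiplicative scale on the intra-module loadings for
#'   this subject (hemoglobin coupling enters here; 1 = nominal).
#' @param affected_module module whose intra loading is reduced by
#'   \code{patient_effect} when \code{group == "patient"}; defaults to the
#'   largest module.
#' @return a \code{subject_record}: list with \code{timeseries}
#'   (\code{n_volumes x n_rois}), \code{motion} (\code{n_volumes x 6}),
#'   \code{confounds} (simulated white-matter and CSF signals),
#'   \code{group}, \code{subject_id}.
#' @export
generate_subject_timeseries <- function(spec, group = c("control", "patient"),
                                        subject_id = "sub", loading_scale = 1,
                                        affected_module = which.max(spec$module_sizes)) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  n <- spec$n_volumes
  n_mod <- length(spec$module_sizes)
  labels <- rep(seq_len(n_mod), spec$module_sizes)

  intra <- rep(spec$intra_loading * loading_scale, n_mod)
  if (group == "patient")
    intra[affected_module] <- intra[affected_module] * spec$patient_effect
  if (any(intra >= 1)) stop("effective intra loading >= 1; reduce scale")

  mod_factors <- vapply(seq_len(n_mod), function(s)
    band_limited_series(n, spec$tr_seconds), numeric(n))
  global_factor <- band_limited_series(n, spec$tr_seconds)

  ts <- matrix(stats::rnorm(n * spec$n_rois, sd = spec$noise_sd),
               nrow = n, ncol = spec$n_rois)
  for (j in seq_len(spec$n_rois)) {
    s <- labels[j]
    ts[, j] <- ts[, j] + intra[s] * mod_factors[, s] +
      spec$inter_loading * global_factor
  }
  colnames(ts) <- sprintf("roi_%04d", seq_len(spec$n_rois))

  motion <- apply(matrix(stats::rnorm(n * 6, sd = spec$motion_step_sd),
                         nrow = n), 2, cumsum)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  confounds <- cbind(wm = band_limited_series(n, spec$tr_seconds),
                     csf = band_limited_series(n, spec$tr_seconds))

  structure(list(subject_id = subject_id, group = group, timeseries = ts,
                 motion = motion, confounds = confounds,
                 covariates = NULL),
            class = "subject_record")
}

#' Generate a full two-group cohort with ground truth
#'
#' Draws clinical covariates per subject (hemoglobin for patients around the
#' anemic values typical of dialysis cohorts, 95.4 g/L SD 22.6; controls
#' around 131.6 g/L SD 12), converts each subject's hemoglobin to a loading
#' scale \code{1 + covariate_coupling * z}, where \code{z} standardizes
#' hemoglobin within the subject's own group, and simulates every subject.
#' Deterministic given \code{spec$seed}.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list with \code{subjects} (list of \code{subject_record}),
#'   \code{ground_truth} (planted partition, affected module, effect,
#'   covariate slope) and \code{spec}.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_mod <- length(spec$module_sizes)
  labels <- rep(seq_len(n_mod), spec$module_sizes)
  affected <- which.max(spec$module_sizes)

  groups <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  n_sub <- length(groups)
  ids <- sprintf("sub_%03d", seq_len(n_sub))

  hb_mean <- ifelse(groups == "patient", 95.4, 131.6)
  hb_sd <- ifelse(groups == "patient", 22.6, 12)
  hemoglobin <- stats::rnorm(n_sub, hb_mean, hb_sd)
  hemoglobin <- pmax(hemoglobin, 40)
  scale <- 1 + spec$covariate_coupling * (hemoglobin - hb_mean) / hb_sd
  scale <- pmin(pmax(scale, 0.2), 1.8)

  age <- ifelse(groups == "patient",
                stats::rnorm(n_sub, 38, 10.5), stats::rnorm(n_sub, 42.1, 8.4))
  age <- pmin(pmax(round(age), 18), 61)
  sex <- stats::rbinom(n_sub, 1L,
                       ifelse(groups == "patient", 16 / 22, 19 / 29))
  albumin <- stats::rnorm(n_sub, ifelse(groups == "patient", 38, 44),
                          ifelse(groups == "patient", 4, 3))
  calcium <- stats::rnorm(n_sub, ifelse(groups == "patient", 2.15, 2.35), 0.12)
  dialysis <- ifelse(groups == "patient",
                     pmax(stats::rnorm(n_sub, 7.4, 2.2), 1), NA_real_)

  subjects <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    rec <- generate_subject_timeseries(spec, groups[i], ids[i],
                                       loading_scale = scale[i],
                                       affected_module = affected)
    rec$covariates <- data.frame(
      subject_id = ids[i], group = groups[i], age = age[i],
      sex = sex[i], hemoglobin = hemoglobin[i], calcium = calcium[i],
      albumin = albumin[i], dialysis_months = dialysis[i],
      stringsAsFactors = FALSE)
    subjects[[i]] <- rec
  }

  list(subjects = subjects,
       ground_truth = list(planted_partition = labels,
                           affected_module = affected,
                           planted_effect = spec$patient_effect,
                           covariate_slope = spec$covariate_coupling),
       spec = spec)
}

#' Clinical covariate table for a cohort
#'
#' One row per subject. Optionally blanks hemoglobin (and calcium) entries
#' for a number of patients, mimicking incomplete laboratory records;
#' downstream partial correlations then run on complete cases only.
#'
#' @param cohort output of \code{\link{generate_cohort}}.
#' @param n_missing_hemoglobin number of patients whose hemoglobin (and
#'   calcium) values are set to \code{NA}.
#' @return data.frame with one row per subject.
#' @export
generate_clinical_table <- function(cohort, n_missing_hemoglobin = 0L) {
  tab <- do.call(rbind, lapply(cohort$subjects, function(s) s$covariates))
  rownames(tab) <- NULL
  if (n_missing_hemoglobin > 0) {
    pat <- which(tab$group == "patient")
    if (n_missing_hemoglobin > length(pat))
      stop("more missing values requested than patients")
    drop <- pat[seq_len(n_missing_hemoglobin)]
    tab$hemoglobin[drop] <- NA_real_
    tab$calcium[drop] <- NA_real_
  }
  tab
}

#' Noise-free population correlation matrix implied by a cohort spec
#'
#' Closed form of the factor model for the control group at nominal loading
#' scale: within-module correlation \eqn{(a^2+b^2)/(a^2+b^2+\sigma^2)},
#' between-module \eqn{b^2/(a^2+b^2+\sigma^2)}. Used for parameter-recovery
#' checks (the planted partition must be the modularity optimum of this
#' matrix).
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return \code{n_rois x n_rois} correlation matrix.
#' @export
population_correlation <- function(spec) {
  a2 <- spec$intra_loading^2
  b2 <- spec$inter_loading^2
  v <- a2 + b2 + spec$noise_sd^2
  labels <- rep(seq_along(spec$module_sizes), spec$module_sizes)
  same <- outer(labels, labels, "==")
  r <- ifelse(same, (a2 + b2) / v, b2 / v)
  diag(r) <- 1
  r
}
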