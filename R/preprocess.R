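#' Discard equilibration volumes and remove linear trends
#'
#' Drops the first \code{n_discard} volumes (T1 equilibration) and removes a
#' least-squares linear trend (intercept + slope) from every ROI column.
#'
#' @param ts numeric matrix, volumes x ROIs.
#' @param n_discard number of leading volumes to drop (default 5).
#' @return detrended matrix with \code{nrow(ts) - n_discard} rows.
#' @export
condition_timeseries <- function(ts, n_discard = 5L) {
  ts <- as.matrix(ts)
  if (n_discard >= nrow(ts)) stop("n_discard must be < number of volumes")
  out <- ts[-seq_len(n_discard), , drop = FALSE]
  if (nrow(out) < 10) stop("fewer than 10 volumes remain after discard")
  t_idx <- seq_len(nrow(out))
  x <- cbind(1, t_idx)
  out - x %*% qr.coef(qr(x), out)
}

#' Zero-phase band-pass filter by frequency-domain masking
#'
#' Retains components in \code{[low_hz, high_hz]} with a 2-bin raised-cosine
#' roll-off on each side; the DC component is always removed. Masking is
#' applied to the DFT, so the filter is zero-phase and exposes no order
#' parameter.
#'
#' @param ts matrix, volumes x ROIs (a vector is treated as one column).
#' @param tr_seconds sampling interval (3 s gives Nyquist 1/6 Hz).
#' @param low_hz,high_hz pass band, default 0.01-0.1 Hz.
#' @return filtered matrix, same dimensions.
#' @export
bandpass_filter <- function(ts, tr_seconds, low_hz = 0.01, high_hz = 0.1) {
  ts <- as.matrix(ts)
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz)) stop("require 0 <= low_hz < high_hz")
  if (high_hz > nyquist + 1e-12)
    stop(sprintf("high_hz (%.4g) exceeds Nyquist frequency %.4g Hz",
                 high_hz, nyquist))
  n <- nrow(ts)
  f <- frequency_grid(n, tr_seconds)
  df <- 1 / (n * tr_seconds)
  mask <- cosine_band_mask(f, low_hz, high_hz, 2 * df)
  mask[f == 0] <- 0
  xf <- stats::mvfft(ts)
  Re(stats::mvfft(xf * mask, inverse = TRUE)) / n
}

# raised-cosine transition of width `roll` outside each band edge
cosine_band_mask <- function(f, low, high, roll) {
  m <- numeric(length(f))
  m[f >= low & f <= high] <- 1
  lo_t <- f < low & f > low - roll
  m[lo_t] <- 0.5 * (1 + cos(pi * (low - f[lo_t]) / roll))
  hi_t <- f > high & f < high + roll
  m[hi_t] <- 0.5 * (1 + cos(pi * (f[hi_t] - high) / roll))
  m
}

#' Friston 24-parameter motion expansion
#'
#' Expands 6 rigid-body parameters into 24 regressors: the 6 parameters,
#' their one-volume backward shifts (first row zero-padded), and the squares
#' of those 12 series, in that fixed column order.
#'
#' @param motion matrix, volumes x 6.
#' @return matrix, volumes x 24, columns named
#'   \code{<p>}, \code{<p>_lag}, \code{<p>_sq}, \code{<p>_lag_sq}.
#' @export
expand_motion_24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion table must have exactly 6 columns")
  lag <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  nm <- colnames(motion)
  if (is.null(nm)) nm <- paste0("m", 1:6)
  out <- cbind(motion, lag, motion^2, lag^2)
  colnames(out) <- c(nm, paste0(nm, "_lag"), paste0(nm, "_sq"),
                     paste0(nm, "_lag_sq"))
  out
}

#' Regress nuisance signals out of ROI time series
#'
#' Replaces every ROI column by its residual from OLS on an intercept plus
#' the nuisance columns. Collinear nuisance columns are dropped (with a
#' warning) via the pivoted QR rank.
#'
#' @param ts matrix, volumes x ROIs.
#' @param nuisance matrix of nuisance regressors, same row count.
#' @return residual matrix, same dimensions as \code{ts}.
#' @export
regress_nuisance <- function(ts, nuisance) {
  ts <- as.matrix(ts)
  nuisance <- as.matrix(nuisance)
  if (nrow(ts) != nrow(nuisance)) stop("row counts of ts and nuisance differ")
  x <- cbind(intercept = 1, nuisance)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning(sprintf("dropping %d collinear nuisance column(s)",
                    ncol(x) - qx$rank))
    qx <- qr(x[, keep, drop = FALSE])
  }
  ts - qr.fitted(qx, ts)
}

#' Frame-wise displacement summaries
#'
#' Scalar FD at volume t: sum of absolute backward differences of the three
#' translations (mm) plus the three rotations converted to arc length on a
#' sphere of \code{head_radius_mm}. Summaries are taken over t >= 2.
#'
#' @param motion matrix, volumes x 6 (translations mm, rotations degrees).
#' @param head_radius_mm radius for the rotation arc length (default 50).
#' @return list with \code{max_fd}, \code{rms_fd}, \code{mean_fd} (mm) and
#'   the per-volume \code{fd} vector.
#' @export
fd_summaries <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) stop("need at least 2 volumes")
  if (ncol(motion) != 6) stop("motion table must have 6 columns")
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * pi / 180 * head_radius_mm
  fd <- rowSums(d)
  list(max_fd = max(fd), rms_fd = sqrt(mean(fd^2)), mean_fd = mean(fd),
       fd = fd)
}

#' Flag a subject for excessive head motion
#'
#' Exceeding 1.5 mm translation or 1.5 degrees rotation in any direction at
#' any volume marks the subject for exclusion; this is a QC flag, not an
#' error.
#'
#' @param motion volumes x 6 matrix.
#' @param max_translation_mm,max_rotation_deg thresholds (default 1.5 each).
#' @return logical.
#' @export
qc_motion_flag <- function(motion, max_translation_mm = 1.5,
                           max_rotation_deg = 1.5) {
  motion <- as.matrix(motion)
  any(abs(motion[, 1:3]) > max_translation_mm) ||
    any(abs(motion[, 4:6]) > max_rotation_deg)
}

#' Full per-subject preprocessing pipeline
#'
#' Fixed stage order: discard + detrend, band-pass, nuisance regression
#' (white-matter and CSF signals, optionally the global signal, and the
#' 24-parameter motion expansion). \code{bandpass_first = FALSE} swaps the
#' last two stages for sensitivity analyses.
#'
#' @param record a \code{subject_record} (see
#'   \code{\link{generate_subject_timeseries}}) or a list with
#'   \code{timeseries}, \code{motion}, and optionally \code{confounds}.
#' @param tr_seconds repetition time.
#' @param n_discard leading volumes to drop (default 5).
#' @param low_hz,high_hz pass band.
#' @param motion_24 include the 24-parameter expansion (default TRUE).
#' @param global_signal regress the mean ROI signal (default FALSE, the
#'   primary analysis; ON reproduces the global-signal-removal variant).
#' @param bandpass_first band-pass before nuisance regression (default TRUE).
#' @return list with the cleaned \code{timeseries}, the aligned
#'   \code{motion} table, \code{motion_summary} (\code{\link{fd_summaries}})
#'   and \code{qc_exclude} flag.
#' @export
preprocess_subject <- function(record, tr_seconds, n_discard = 5L,
                               low_hz = 0.01, high_hz = 0.1,
                               motion_24 = TRUE, global_signal = FALSE,
                               bandpass_first = TRUE) {
  ts <- condition_timeseries(record$timeseries, n_discard)
  motion <- as.matrix(record$motion)[-seq_len(n_discard), , drop = FALSE]

  nuis <- if (motion_24) expand_motion_24(motion) else motion
  if (!is.null(record$confounds)) {
    conf <- as.matrix(record$confounds)[-seq_len(n_discard), , drop = FALSE]
    nuis <- cbind(conf, nuis)
  }
  if (global_signal) nuis <- cbind(global = rowMeans(ts), nuis)

  if (bandpass_first) {
    ts <- bandpass_filter(ts, tr_seconds, low_hz, high_hz)
    ts <- regress_nuisance(ts, nuis)
  } else {
    ts <- regress_nuisance(ts, nuis)
    ts <- bandpass_filter(ts, tr_seconds, low_hz, high_hz)
  }
  list(timeseries = ts, motion = motion,
       motion_summary = fd_summaries(record$motion),
       qc_exclude = qc_motion_flag(record$motion))
}
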