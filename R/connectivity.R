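# Preprocessing from ROI time series to Fisher-z connectivity:
# scrubbing by framewise displacement, 36-parameter nuisance regression,
# first-order Butterworth band-pass, Pearson correlation + Fisher z.

#' Framewise displacement from rigid-body motion parameters
#'
#' FD at volume t is the sum of absolute backward differences of the three
#' translations (mm) plus the three rotations converted to arc length on a
#' sphere of radius `head_radius_mm` (Power convention). The first volume
#' has FD 0.
#'
#' @param motion T x 6 numeric matrix: translations (mm) then rotations
#'   (radians).
#' @param head_radius_mm Head radius used to convert rotations to mm.
#' @return Numeric vector of length T (mm).
#' @export
compute_fd <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns", call. = FALSE)
  if (nrow(motion) < 2) stop("need at least 2 volumes", call. = FALSE)
  if (!all(is.finite(motion))) stop("non-finite motion values", call. = FALSE)
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * head_radius_mm
  c(0, rowSums(d))
}

#' Scrub high-motion volumes
#'
#' @param fd Per-volume framewise displacement (mm).
#' @param threshold Volumes with `fd > threshold` are removed (field-standard default
#'   0.5 mm).
#' @return List with logical `keep` mask and `n_removed`.
#' @export
scrub_volumes <- function(fd, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("scrub threshold must be a positive number", call. = FALSE)
  }
  keep <- !(fd > threshold)
  list(keep = keep, n_removed = sum(!keep))
}

#' Build the 36-parameter nuisance design
#'
#' Nine base regressors (six motion parameters plus global, white-matter and
#' CSF mean signals), their backward-difference temporal derivatives (first
#' row zero), and the squares of all eighteen.
#'
#' @param motion T x 6 motion matrix.
#' @param global_signal,wm_signal,csf_signal Length-T tissue mean signals.
#' @return T x 36 numeric matrix with descriptive column names.
#' @export
build_nuisance_design <- function(motion, global_signal, wm_signal, csf_signal) {
  motion <- as.matrix(motion)
  T_ <- nrow(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns", call. = FALSE)
  sig <- cbind(global_signal, wm_signal, csf_signal)
  if (nrow(sig) != T_) stop("tissue signals must match motion length", call. = FALSE)
  base <- cbind(motion, sig)
  colnames(base) <- c(paste0("motion", 1:6), "gs", "wm", "csf")
  deriv <- rbind(0, diff(base))
  colnames(deriv) <- paste0("d_", colnames(base))
  lin <- cbind(base, deriv)
  quad <- lin^2
  colnames(quad) <- paste0("sq_", colnames(lin))
  out <- cbind(lin, quad)
  stopifnot(ncol(out) == 36)
  out
}

#' Regress nuisance signals out of ROI time series
#'
#' Ordinary least squares of each ROI time course on the design plus an
#' intercept; returns the residuals. A rank-deficient design triggers a
#' warning and a pseudo-inverse fit.
#'
#' @param series T x K ROI time-series matrix.
#' @param design T x q nuisance design (typically from
#'   [build_nuisance_design()]).
#' @return T x K matrix of residuals.
#' @export
regress_nuisance <- function(series, design) {
  series <- as.matrix(series)
  design <- as.matrix(design)
  if (nrow(series) != nrow(design)) {
    stop("series and design must have the same number of rows", call. = FALSE)
  }
  if (nrow(design) <= ncol(design) + 1) {
    stop("need more volumes than regressors + intercept", call. = FALSE)
  }
  X <- cbind(1, design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient nuisance design; using pseudo-inverse fit",
            call. = FALSE)
    beta <- MASS::ginv(X) %*% series
    return(series - X %*% beta)
  }
  series - X %*% qr.coef(qrX, series)
}

#' Zero-phase Butterworth band-pass filter
#'
#' First-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`) for zero phase distortion.
#'
#' @param series T x K matrix (or vector) of time courses.
#' @param tr_seconds Repetition time in seconds.
#' @param low_hz,high_hz Pass band edges (field-standard defaults 0.01 and 0.08 Hz).
#' @return Filtered series, same shape as input.
#' @export
bandpass_filter <- function(series, tr_seconds, low_hz = 0.01, high_hz = 0.08) {
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist)) {
    stop(sprintf("band [%g, %g] Hz outside (0, Nyquist = %g)",
                 low_hz, high_hz, nyquist), call. = FALSE)
  }
  bf <- signal::butter(1, c(low_hz, high_hz) / nyquist, type = "pass")
  vec <- is.null(dim(series))
  series <- as.matrix(series)
  # remove the DC component first: it lies outside the pass band and
  # otherwise produces large start-up transients in the recursive filter
  series <- sweep(series, 2, colMeans(series))
  out <- apply(series, 2, function(x) signal::filtfilt(bf, x))
  if (vec) out <- drop(out)
  out
}

#' Fisher-z connectivity from residual time series
#'
#' Pearson correlations over retained volumes between every node pair in the
#' edge-index ordering, Fisher z transformed (with the finite cap at
#' |r| = 1). A zero-variance ROI yields `NA` at its edges and is reported.
#'
#' @param series T x K residual time series.
#' @param edge_index [build_edge_index()] object with `n_nodes == K`.
#' @param keep Optional logical mask of retained volumes.
#' @return List with `z` (edge vector), `flagged_rois` (integer indices of
#'   zero-variance ROIs).
#' @export
compute_connectivity <- function(series, edge_index, keep = NULL) {
  stopifnot(inherits(edge_index, "edge_index"))
  series <- as.matrix(series)
  if (ncol(series) != edge_index$n_nodes) {
    stop("series has wrong number of ROIs", call. = FALSE)
  }
  if (!is.null(keep)) series <- series[keep, , drop = FALSE]
  if (nrow(series) < 3) stop("need at least 3 retained volumes", call. = FALSE)
  sds <- apply(series, 2, stats::sd)
  flagged <- unname(which(sds == 0))
  r <- suppressWarnings(stats::cor(series))
  z <- fisher_z(r[cbind(edge_index$i, edge_index$j)])
  list(z = z, flagged_rois = flagged)
}

#' Flag subjects with outlying scrub counts
#'
#' Excludes subjects whose removed-volume count lies more than 3 standard
#' deviations above the mean removed count across subjects (direction
#' selectable: the alternative reading flags retained counts below
#' mean - 3 SD of retained counts).
#'
#' @param removed_counts Named numeric vector of removed volumes per subject.
#' @param n_sd Number of standard deviations (default 3).
#' @param direction `"removed_above"` (default) or `"retained_below"`.
#' @param total_volumes Required for `direction = "retained_below"`.
#' @return Character vector of excluded subject names (indices if unnamed).
#' @export
exclusion_check <- function(removed_counts, n_sd = 3,
                            direction = c("removed_above", "retained_below"),
                            total_volumes = NULL) {
  direction <- match.arg(direction)
  if (length(removed_counts) < 2) stop("need at least 2 subjects", call. = FALSE)
  ids <- names(removed_counts)
  if (is.null(ids)) ids <- as.character(seq_along(removed_counts))
  if (direction == "removed_above") {
    thr <- mean(removed_counts) + n_sd * stats::sd(removed_counts)
    out <- removed_counts > thr
  } else {
    if (is.null(total_volumes)) {
      stop("'total_volumes' required for direction = 'retained_below'",
           call. = FALSE)
    }
    retained <- total_volumes - removed_counts
    thr <- mean(retained) - n_sd * stats::sd(retained)
    out <- retained < thr
  }
  ids[out]
}

#' Full preprocessing pipeline for one scan
#'
#' Fixed stage order: scrub (volume deletion) -> nuisance regression ->
#' band-pass filtering on the concatenated retained series -> correlation.
#'
#' @param series T x K ROI time series.
#' @param motion T x 6 motion parameters.
#' @param edge_index Edge index for K nodes.
#' @param tr_seconds Repetition time (s).
#' @param fd_threshold Scrub threshold in mm.
#' @param head_radius_mm Head radius for FD rotation scaling.
#' @param low_hz,high_hz Band-pass edges.
#' @return List with `z` (edge vector), `fd`, `n_removed`, `flagged_rois`.
#' @export
connectivity_pipeline <- function(series, motion, edge_index, tr_seconds,
                                  fd_threshold = 0.5, head_radius_mm = 50,
                                  low_hz = 0.01, high_hz = 0.08) {
  fd <- compute_fd(motion, head_radius_mm)
  scrub <- scrub_volumes(fd, fd_threshold)
  kept <- series[scrub$keep, , drop = FALSE]
  mkept <- motion[scrub$keep, , drop = FALSE]
  gs <- rowMeans(kept)
  # tissue means are taken from the ROI series itself here; real pipelines
  # supply segmented WM/CSF signals
  design <- build_nuisance_design(mkept, gs, gs, gs)
  # drop duplicated tissue columns to avoid an artificially singular design
  design <- design[, !duplicated(t(design)), drop = FALSE]
  resid <- regress_nuisance(kept, design)
  filtered <- bandpass_filter(resid, tr_seconds, low_hz, high_hz)
  conn <- compute_connectivity(filtered, edge_index)
  list(z = conn$z, fd = fd, n_removed = scrub$n_removed,
       flagged_rois = conn$flagged_rois)
}
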