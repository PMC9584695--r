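#' BOLD time-series container
#'
#' Bundles a 4D BOLD array with its voxel geometry, repetition time, and
#' brain mask. Data are stored in NIfTI axis order (x, y, z, t).
#'
#' @param data 4D numeric array, dimensions x-y-z-t.
#' @param voxel_size_mm Length-3 positive numeric, voxel edge lengths in mm.
#' @param tr_seconds Positive scalar, repetition time in seconds.
#' @param mask 3D logical array matching the spatial dimensions of `data`.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, voxel_size_mm = c(3, 3, 3), tr_seconds = 2,
                        mask = NULL) {
  if (length(dim(data)) != 4L) stop_field("data", "must be a 4D array")
  nt <- dim(data)[4]
  if (nt < 2L) stop_field("data", "needs at least 2 time points")
  if (any(voxel_size_mm <= 0) || length(voxel_size_mm) != 3L)
    stop_field("voxel_size_mm", "must be 3 positive reals")
  check_real(tr_seconds, "tr_seconds", 0, open_lower = TRUE)
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  if (!identical(dim(mask), dim(data)[1:3]))
    stop_field("mask", "spatial dimensions must match the BOLD data")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_seconds = tr_seconds, mask = array(as.logical(mask), dim(mask))),
            class = "bold_series")
}

n_timepoints <- function(bold) dim(bold$data)[4]

#' Discard initial volumes
#'
#' Removes the first `n_discard` volumes acquired before magnetization
#' equilibrium (10 by convention for a 210-volume acquisition).
#'
#' @param bold A [bold_series()].
#' @param n_discard Number of leading volumes to drop.
#' @return A `bold_series` with `n_discard` fewer time points.
#' @export
discard_initial <- function(bold, n_discard = 10L) {
  n_discard <- check_count(n_discard, "n_discard", min = 0L)
  nt <- n_timepoints(bold)
  if (nt <= n_discard)
    stop(sprintf("cannot discard %d volumes from a %d-volume series",
                 n_discard, nt), call. = FALSE)
  if (n_discard == 0L) return(bold)
  bold$data <- bold$data[, , , (n_discard + 1L):nt, drop = FALSE]
  bold
}

#' Drop motion-parameter rows for discarded volumes
#' @param motion T x 6 numeric matrix of realignment parameters.
#' @param n_discard Number of leading rows to drop.
#' @return Matrix with `n_discard` fewer rows.
#' @export
discard_motion <- function(motion, n_discard = 10L) {
  motion <- as_motion(motion)
  n_discard <- check_count(n_discard, "n_discard", min = 0L)
  if (nrow(motion) <= n_discard) stop("too few motion rows", call. = FALSE)
  motion[(n_discard + 1L):nrow(motion), , drop = FALSE]
}

as_motion <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion parameters must have 6 columns (3 translations mm, 3 rotations rad)",
         call. = FALSE)
  storage.mode(motion) <- "double"
  motion
}

#' Frame-wise displacement and motion exclusion
#'
#' Power-style FD: for each pair of consecutive volumes, the sum of absolute
#' translation differences (mm) plus the head-radius-scaled sum of absolute
#' rotation differences (radians on a 50 mm sphere). The exclusion flag is
#' raised when any realignment parameter exceeds 2 mm translation or 2
#' degrees rotation in absolute value.
#'
#' @param motion T x 6 matrix: columns 1-3 translations (mm), 4-6 rotations
#'   (radians).
#' @param head_radius_mm Sphere radius converting rotations to arc length.
#' @param max_translation_mm,max_rotation_deg Exclusion thresholds.
#' @return List with `fd_series` (length T-1), `mean_fd`, and `excluded`.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50,
                                   max_translation_mm = 2,
                                   max_rotation_deg = 2) {
  motion <- as_motion(motion)
  if (nrow(motion) < 2L) stop("need at least 2 volumes for FD", call. = FALSE)
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  excluded <- any(abs(motion[, 1:3]) > max_translation_mm) ||
    any(abs(motion[, 4:6]) > max_rotation_deg * pi / 180)
  list(fd_series = as.numeric(fd), mean_fd = mean(fd), excluded = excluded)
}

#' Friston-24 + global-signal confound matrix
#'
#' Columns 1-6: realignment parameters; 7-12: the same parameters lagged one
#' volume (first row zero); 13-24: squares of columns 1-12; 25: global
#' signal (per-volume mean over in-mask voxels).
#'
#' @param motion T x 6 matrix aligned with the (post-discard) BOLD series.
#' @param bold A [bold_series()] supplying the global signal.
#' @return List with `matrix` (T x 25) and `column_names`.
#' @export
build_confounds <- function(motion, bold) {
  motion <- as_motion(motion)
  nt <- n_timepoints(bold)
  if (nrow(motion) != nt)
    stop(sprintf("motion has %d rows but BOLD has %d volumes",
                 nrow(motion), nt), call. = FALSE)
  lagged <- rbind(0, motion[-nt, , drop = FALSE])
  friston <- cbind(motion, lagged, motion^2, lagged^2)
  idx <- mask_indices(bold$mask)
  mat <- matrix(bold$data, prod(dim(bold$data)[1:3]), nt)
  global <- colMeans(mat[idx, , drop = FALSE])
  nm <- c(paste0("mp", 1:6), paste0("mp_lag", 1:6),
          paste0("mp_sq", 1:6), paste0("mp_lag_sq", 1:6), "global_signal")
  out <- cbind(friston, global)
  colnames(out) <- nm
  list(matrix = out, column_names = nm)
}

#' Regress nuisance confounds out of every in-mask voxel
#'
#' Each in-mask voxel time series is replaced by its least-squares residual
#' against an intercept plus the confound columns. Constant (zero-variance)
#' confound columns are dropped before fitting; a rank-deficient design
#' after the drop is an error naming the collinear columns.
#'
#' @param bold A [bold_series()].
#' @param confounds Result of [build_confounds()] or a T x k numeric matrix.
#' @return A `bold_series` of residuals (out-of-mask voxels zeroed).
#' @export
regress_confounds <- function(bold, confounds) {
  cm <- if (is.list(confounds) && !is.null(confounds$matrix)) confounds$matrix
        else as.matrix(confounds)
  nt <- n_timepoints(bold)
  if (nrow(cm) != nt)
    stop("confound rows must equal the number of BOLD volumes", call. = FALSE)
  keep <- apply(cm, 2, function(col) stats::sd(col) > 0)
  cm_kept <- cm[, keep, drop = FALSE]
  X <- cbind(intercept = 1, cm_kept)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("confound matrix is rank deficient; collinear columns: %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  idx <- mask_indices(bold$mask)
  nv_all <- prod(dim(bold$data)[1:3])
  mat <- matrix(bold$data, nv_all, nt)
  Y <- t(mat[idx, , drop = FALSE])                       # T x V
  res <- qr.resid(qrX, Y)
  out <- matrix(0, nv_all, nt)
  out[idx, ] <- t(res)
  bold$data <- array(out, dim(bold$data))
  bold
}

#' Ideal frequency-domain band-pass filter
#'
#' Demeans each in-mask voxel series, then zeroes all discrete-Fourier bins
#' whose frequency lies outside `[low_hz, high_hz]` (bin-inclusive edges)
#' and inverts the transform. The zero-frequency (mean) bin is always
#' removed.
#'
#' @param bold A [bold_series()].
#' @param low_hz,high_hz Pass-band edges in Hz; defaults 0.01-0.08.
#' @return A filtered `bold_series` (out-of-mask voxels zeroed).
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.08) {
  tr <- bold$tr_seconds
  nyquist <- 1 / (2 * tr)
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  if (high_hz >= nyquist)
    stop(sprintf("high edge %.4g Hz must be below Nyquist %.4g Hz",
                 high_hz, nyquist), call. = FALSE)
  nt <- n_timepoints(bold)
  freqs <- seq(0, nt - 1) / (nt * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)                  # fold negative bins
  keep <- freqs >= low_hz & freqs <= high_hz
  idx <- mask_indices(bold$mask)
  nv_all <- prod(dim(bold$data)[1:3])
  mat <- matrix(bold$data, nv_all, nt)
  Y <- t(mat[idx, , drop = FALSE])                      # T x V
  Y <- sweep(Y, 2, colMeans(Y))
  spec <- stats::mvfft(Y)
  spec[!keep, ] <- 0
  filt <- Re(stats::mvfft(spec, inverse = TRUE)) / nt
  out <- matrix(0, nv_all, nt)
  out[idx, ] <- t(filt)
  bold$data <- array(out, dim(bold$data))
  bold
}

#' Run the full temporal preprocessing chain on one subject
#'
#' discard -> FD/exclusion check -> Friston-24 + global-signal regression ->
#' band-pass, in that order. Motion rows for discarded volumes are dropped
#' before confound construction; the exclusion rule is evaluated on the
#' post-discard motion trace.
#'
#' @param bold A [bold_series()] including the to-be-discarded volumes.
#' @param motion Motion matrix with one row per input volume.
#' @param n_discard Leading volumes to drop.
#' @param low_hz,high_hz Band-pass edges.
#' @param global_signal Include the global-signal column?
#' @return List with `bold` (preprocessed), `fd` (the FD summary), and
#'   `excluded`.
#' @export
preprocess_subject <- function(bold, motion, n_discard = 10L,
                               low_hz = 0.01, high_hz = 0.08,
                               global_signal = TRUE) {
  motion <- as_motion(motion)
  if (nrow(motion) != n_timepoints(bold))
    stop("motion rows must match BOLD volumes before discard", call. = FALSE)
  bold <- discard_initial(bold, n_discard)
  motion <- discard_motion(motion, n_discard)
  fd <- framewise_displacement(motion)
  conf <- build_confounds(motion, bold)
  if (!global_signal)
    conf$matrix <- conf$matrix[, colnames(conf$matrix) != "global_signal",
                               drop = FALSE]
  bold <- regress_confounds(bold, conf$matrix)
  bold <- bandpass(bold, low_hz, high_hz)
  list(bold = bold, fd = fd, excluded = fd$excluded)
}
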