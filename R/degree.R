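#' Degree-centrality parameters
#'
#' Defaults reproduce the standard voxelwise-connectome settings: edges are
#' Pearson correlations strictly greater than 0.25, degree is the binary
#' edge count, and the z-scored map is smoothed with a 6 mm FWHM Gaussian.
#'
#' @param r_threshold Correlation threshold; an edge exists when r is
#'   strictly greater than this value (signed r, not |r|).
#' @param fwhm_mm Smoothing kernel full width at half maximum in mm.
#' @param binary_degree If `TRUE` degree counts suprathreshold edges; if
#'   `FALSE` it sums their correlation weights.
#' @param chunk_size Voxels per correlation block; the full V x V matrix is
#'   never materialized when V exceeds this.
#' @return A list of class `dc_params`.
#' @export
dc_params <- function(r_threshold = 0.25, fwhm_mm = 6, binary_degree = TRUE,
                      chunk_size = 512L) {
  check_real(r_threshold, "r_threshold", -1, 1, TRUE, TRUE)
  check_real(fwhm_mm, "fwhm_mm", 0)
  chunk_size <- check_count(chunk_size, "chunk_size")
  structure(list(r_threshold = r_threshold, fwhm_mm = fwhm_mm,
                 binary_degree = isTRUE(binary_degree),
                 chunk_size = chunk_size), class = "dc_params")
}

#' Voxel degree from a time-by-voxel matrix
#'
#' For each voxel i, degree_i counts (binary) or sums (weighted) the
#' correlations r_ij > threshold over all other voxels j. Self-edges are
#' excluded. Correlations are computed block-wise over columns so memory
#' stays at V x chunk_size. Zero-variance voxels contribute no edges; their
#' count is returned in the `n_degenerate` attribute and a warning is
#' emitted.
#'
#' @param ts T x V numeric matrix of time courses.
#' @param params A [dc_params()].
#' @return Length-V numeric degree vector with attribute `n_degenerate`.
#' @export
degree_from_timeseries <- function(ts, params = dc_params()) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 time points", call. = FALSE)
  v <- ncol(ts)
  ctr <- sweep(ts, 2, colMeans(ts))
  ss <- sqrt(colSums(ctr^2))
  degen <- ss == 0
  if (any(degen)) {
    warning(sprintf("%d zero-variance voxel(s) contribute no edges",
                    sum(degen)), call. = FALSE)
    ss[degen] <- 1                       # standardized column becomes all-zero
  }
  z <- sweep(ctr, 2, ss, "/")            # crossprod(z) is the correlation matrix
  thr <- params$r_threshold
  degree <- numeric(v)
  starts <- seq(1L, v, by = params$chunk_size)
  for (s in starts) {
    cols <- s:min(s + params$chunk_size - 1L, v)
    r <- crossprod(z, z[, cols, drop = FALSE])   # V x block
    edge <- r > thr
    if (any(degen)) edge[degen, ] <- FALSE       # no edges from degenerate voxels
    # remove the self-correlation (r_ii = 1 > thr) for non-degenerate voxels
    self <- as.numeric(!degen[cols] & 1 > thr)
    if (params$binary_degree) {
      degree[cols] <- colSums(edge) - self
    } else {
      degree[cols] <- colSums(r * edge) - self
    }
  }
  degree[degen] <- 0
  attr(degree, "n_degenerate") <- sum(degen)
  degree
}

#' z-score a degree map over the mask
#'
#' z = (degree - in-mask mean) / in-mask sample SD; voxels outside the mask
#' are set to zero.
#'
#' @param volume 3D numeric array of raw degrees.
#' @param mask 3D logical array.
#' @return 3D numeric array of z scores.
#' @export
zscore_map <- function(volume, mask) {
  idx <- mask_indices(mask)
  vals <- volume[idx]
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0)
    stop("degree map has zero variance over the mask; z map is uninformative",
         call. = FALSE)
  out <- array(0, dim(volume))
  out[idx] <- (vals - mean(vals)) / s
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  radius <- max(1L, ceiling(4 * sigma_vox))
  x <- -radius:radius
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D convolution along the first dimension of a (n x m) matrix with
# reflect-boundary padding (edge value mirrored without repetition).
conv_reflect <- function(mat, kernel) {
  n <- nrow(mat)
  radius <- (length(kernel) - 1L) / 2L
  if (radius == 0L) return(mat)
  refl <- function(i) {                    # mirror boundary, period 2n - 2
    if (n == 1L) return(rep(1L, length(i)))
    j <- (i - 1L) %% (2L * n - 2L)
    j[j < 0] <- j[j < 0] + 2L * n - 2L
    j[j >= n] <- 2L * n - 2L - j[j >= n]
    j + 1L
  }
  out <- matrix(0, n, ncol(mat))
  for (k in seq_along(kernel)) {
    off <- k - radius - 1L
    out <- out + kernel[k] * mat[refl(seq_len(n) + off), , drop = FALSE]
  }
  out
}

#' Separable 3D Gaussian smoothing
#'
#' Per-axis sigma in voxels is `fwhm_mm / (voxel_size_mm * 2 * sqrt(2*log(2)))`.
#' The kernel is normalized to unit sum and the boundary is handled by
#' reflection, so constant volumes pass through unchanged. `fwhm_mm = 0` is
#' the identity.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm Kernel full width at half maximum in mm.
#' @param voxel_size_mm Length-3 voxel edge lengths in mm.
#' @return Smoothed 3D array.
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size_mm = c(3, 3, 3)) {
  check_real(fwhm_mm, "fwhm_mm", 0)
  if (fwhm_mm == 0) return(volume)
  d <- dim(volume)
  sigmas <- fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))
  x <- volume
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    m <- matrix(xp, d[axis])
    m <- conv_reflect(m, gaussian_kernel_1d(sigmas[axis]))
    xp <- array(m, dim(xp))
    x <- aperm(xp, order(perm))
  }
  x
}

#' Full degree-centrality map for one preprocessed subject
#'
#' Extracts the in-mask T x V matrix, computes voxel degrees over the
#' thresholded correlation graph, z-scores them over the mask, and smooths
#' the z map. All three stages are kept.
#'
#' @param bold A preprocessed [bold_series()].
#' @param params A [dc_params()].
#' @return Object of class `dc_map` with fields `raw_degree`, `z_map`,
#'   `smoothed_z` (3D arrays), `mask`, `n_voxels`, and `params`.
#' @export
compute_dc_map <- function(bold, params = dc_params()) {
  idx <- mask_indices(bold$mask)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  nt <- n_timepoints(bold)
  mat <- matrix(bold$data, prod(dim(bold$data)[1:3]), nt)
  ts <- t(mat[idx, , drop = FALSE])
  degree <- degree_from_timeseries(ts, params)
  raw <- array(0, dim(bold$mask))
  raw[idx] <- degree
  z <- zscore_map(raw, bold$mask)
  sm <- gaussian_smooth(z, params$fwhm_mm, bold$voxel_size_mm)
  structure(list(raw_degree = raw, z_map = z, smoothed_z = sm,
                 mask = bold$mask, n_voxels = length(idx), params = params),
            class = "dc_map")
}
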