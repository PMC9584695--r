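#' Stack smoothed z maps into a subjects-by-voxels matrix
#' @param dc_maps List of `dc_map` objects sharing geometry.
#' @param mask 3D logical array (defaults to the first map's mask).
#' @param layer Which stored map to extract.
#' @return n_subjects x n_voxels numeric matrix.
#' @export
stack_dc_maps <- function(dc_maps, mask = NULL,
                          layer = c("smoothed_z", "z_map", "raw_degree")) {
  layer <- match.arg(layer)
  if (is.null(mask)) mask <- dc_maps[[1]]$mask
  idx <- mask_indices(mask)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  t(vapply(dc_maps, function(m) {
    if (!identical(dim(m[[layer]]), dim(mask)))
      stop("map geometry does not match the mask", call. = FALSE)
    m[[layer]][idx]
  }, numeric(length(idx))))
}

# Voxelwise GLM t statistic for one design column across a response matrix.
# Y: n x V; X: n x p design (intercept included by the caller);
# coef_index: the column whose t is wanted.
glm_tmap <- function(Y, X, coef_index) {
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  n <- nrow(X)
  df <- n - ncol(X)
  if (df < 1L) stop("not enough subjects for the design", call. = FALSE)
  XtX <- crossprod(X)
  XtXinv <- solve(XtX)
  beta <- solve(XtX, crossprod(X, Y))
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXinv[coef_index, coef_index])
  t <- beta[coef_index, ] / se
  t[se == 0] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, df = df)
}

design_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0))
    return(matrix(numeric(0), n, 0))
  cm <- as.matrix(covariates)
  if (nrow(cm) != n) stop("covariate rows must match subjects", call. = FALSE)
  if (anyNA(cm)) stop("covariates contain missing values", call. = FALSE)
  storage.mode(cm) <- "double"
  cm
}

as_stat_map <- function(t, p, df, mask, kind) {
  idx <- mask_indices(mask)
  tm <- array(0, dim(mask)); pm <- array(1, dim(mask))
  tm[idx] <- t; pm[idx] <- p
  structure(list(t_map = tm, p_map = pm, df = df, test_kind = kind,
                 mask = mask), class = "stat_map")
}

#' Covariate-adjusted voxelwise two-sample t map
#'
#' Per voxel fits `dc ~ intercept + group + covariates` by least squares and
#' reports the t statistic of the group coefficient (group A coded 1,
#' group B coded 0) with df = n - rank(design). With no covariates this
#' reproduces the classical pooled two-sample t test.
#'
#' @param dcA,dcB Lists of `dc_map` objects for the two groups, or numeric
#'   matrices (subjects x voxels).
#' @param covariates Optional data frame / matrix (e.g. age, gender,
#'   education, mean FD), rows ordered as `c(A, B)`.
#' @param mask 3D logical array (required when matrices are passed).
#' @return A `stat_map` (two-sided p values).
#' @export
voxelwise_two_sample <- function(dcA, dcB, covariates = NULL, mask = NULL) {
  YA <- if (is.matrix(dcA)) dcA else stack_dc_maps(dcA, mask)
  YB <- if (is.matrix(dcB)) dcB else stack_dc_maps(dcB, mask)
  if (is.null(mask)) mask <- dcA[[1]]$mask
  nA <- nrow(YA); nB <- nrow(YB)
  Y <- rbind(YA, YB)
  cm <- design_matrix(covariates, nA + nB)
  if (nA + nB < ncol(cm) + 3L)
    stop("too few subjects for the covariate design", call. = FALSE)
  X <- cbind(1, c(rep(1, nA), rep(0, nB)), cm)
  fit <- glm_tmap(Y, X, coef_index = 2L)
  as_stat_map(fit$t, fit$p, fit$df, mask, "two_sample")
}

#' Covariate-adjusted voxelwise paired t map
#'
#' Computes within-subject differences (first minus second session) per
#' voxel and fits a one-sample GLM with mean-centered covariates; the
#' intercept t is the adjusted mean paired difference. With no covariates
#' this is the classical paired t test.
#'
#' @param dc_t1,dc_t2 Equal-length lists of `dc_map` objects (or matrices),
#'   paired by position.
#' @param covariates Optional per-subject covariates.
#' @param mask 3D logical array.
#' @return A `stat_map`.
#' @export
voxelwise_paired <- function(dc_t1, dc_t2, covariates = NULL, mask = NULL) {
  Y1 <- if (is.matrix(dc_t1)) dc_t1 else stack_dc_maps(dc_t1, mask)
  Y2 <- if (is.matrix(dc_t2)) dc_t2 else stack_dc_maps(dc_t2, mask)
  if (is.null(mask)) mask <- dc_t1[[1]]$mask
  if (nrow(Y1) != nrow(Y2))
    stop("paired lists must have equal length", call. = FALSE)
  D <- Y1 - Y2
  cm <- design_matrix(covariates, nrow(D))
  if (ncol(cm) > 0) cm <- scale(cm, center = TRUE, scale = FALSE)
  X <- cbind(1, cm)
  fit <- glm_tmap(D, X, coef_index = 1L)
  as_stat_map(fit$t, fit$p, fit$df, mask, "paired")
}

#' Benjamini-Hochberg FDR feature mask
#'
#' Applies the BH step-up procedure to the in-mask p values and returns the
#' binary mask of voxels significant at level `q`.
#'
#' @param stat_map A `stat_map`.
#' @param q FDR level (default 0.05).
#' @return List of class `feature_mask`: `mask` (3D logical), `n_voxels`,
#'   `provenance`.
#' @export
fdr_correct <- function(stat_map, q = 0.05) {
  check_real(q, "q", 0, 1, TRUE, TRUE)
  idx <- mask_indices(stat_map$mask)
  if (length(idx) == 0L) stop("empty analysis mask", call. = FALSE)
  padj <- stats::p.adjust(stat_map$p_map[idx], method = "BH")
  sig <- array(FALSE, dim(stat_map$mask))
  sig[idx] <- padj <= q
  structure(list(mask = sig, n_voxels = sum(sig),
                 provenance = sprintf("%s t map, BH-FDR q = %g",
                                      stat_map$test_kind, q)),
            class = "feature_mask")
}

#' Two-sample pooled t test from summary statistics
#'
#' Student's t with pooled variance and df = n1 + n2 - 2, as used for
#' group demographic tables reported as mean and SD.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive", call. = FALSE)
  n1 <- check_count(n1, "n1", 2L); n2 <- check_count(n2, "n2", 2L)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 count table
#'
#' No continuity correction, matching standard contingency reporting for
#' gender counts.
#'
#' @param counts 2x2 nonnegative matrix.
#' @return List with `chi2`, `df`, `p`.
#' @export
chi_square_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L)) || any(counts < 0))
    stop("need a 2x2 table of nonnegative counts", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("table has a zero margin", call. = FALSE)
  res <- stats::chisq.test(counts, correct = FALSE)
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
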