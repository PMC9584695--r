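test_that("degree counts suprathreshold correlations with strict inequality", {
  # three identical non-constant columns: r = 1 everywhere off-diagonal
  x <- rnorm(30)
  ts <- cbind(x, x, x)
  expect_equal(as.numeric(degree_from_timeseries(ts)), c(2, 2, 2))

  # a pair correlating exactly at the threshold forms no edge
  a <- c(1, -1, 0, 0); z <- c(0, 0, 1, -1)
  y <- a + sqrt(15) * z
  r_exact <- cor(a, y)
  deg <- degree_from_timeseries(cbind(a, y),
                                dc_params(r_threshold = r_exact))
  expect_equal(as.numeric(deg), c(0, 0))
})

test_that("block-wise degree equals the all-pairs double-loop oracle", {
  set.seed(42)
  ts <- matrix(rnorm(20 * 40), 20, 40)
  p <- dc_params(chunk_size = 7)
  expect_equal(as.numeric(degree_from_timeseries(ts, p)),
               as.numeric(pairloop_degree(ts)))
  # weighted mode against the matrix oracle
  pw <- dc_params(chunk_size = 7, binary_degree = FALSE)
  expect_equal(as.numeric(degree_from_timeseries(ts, pw)),
               naive_degree(ts, binary = FALSE), tolerance = 1e-12)
})

test_that("zero-variance voxels contribute no edges and warn", {
  set.seed(2)
  ts <- matrix(rnorm(25 * 6), 25, 6)
  ts[, 3] <- 5
  expect_warning(deg <- degree_from_timeseries(ts), "zero-variance")
  expect_equal(deg[3], 0)
  expect_equal(attr(deg, "n_degenerate"), 1)
  # remaining degrees agree with the oracle on the non-degenerate columns
  expect_equal(as.numeric(deg[-3]), pairloop_degree(ts[, -3]))
  # even with a negative threshold a degenerate voxel stays isolated
  expect_warning(degn <- degree_from_timeseries(ts, dc_params(r_threshold = -0.5)))
  expect_equal(degn[3], 0)
})

test_that("degree respects graph symmetry and threshold monotonicity", {
  set.seed(9)
  ts <- matrix(rnorm(20 * 50), 20, 50)
  deg <- degree_from_timeseries(ts)
  expect_equal(sum(deg) %% 2, 0)
  for (thr in c(0.1, 0.25, 0.5)) {
    lo <- degree_from_timeseries(ts, dc_params(r_threshold = thr))
    hi <- degree_from_timeseries(ts, dc_params(r_threshold = thr + 0.2))
    expect_true(all(hi <= lo))
  }
})

test_that("z-scoring normalizes over the mask and is affine invariant", {
  mask <- array(TRUE, c(3, 1, 1))
  vol <- array(c(1, 2, 3), c(3, 1, 1))
  expect_equal(as.numeric(zscore_map(vol, mask)), c(-1, 0, 1))

  set.seed(3)
  vol2 <- array(rnorm(64), c(4, 4, 4))
  mask2 <- array(runif(64) > 0.3, c(4, 4, 4))
  z <- zscore_map(vol2, mask2)
  expect_lt(abs(mean(z[mask2])), 1e-10)
  expect_lt(abs(sd(z[mask2]) - 1), 1e-10)
  expect_true(all(z[!mask2] == 0))
  # affine transform of the degrees changes nothing
  z2 <- zscore_map(array(2.5 * vol2 + 7, dim(vol2)), mask2)
  expect_equal(z, z2, tolerance = 1e-10)

  expect_error(zscore_map(array(1, c(2, 2, 2)), array(TRUE, c(2, 2, 2))),
               "zero variance")
})

test_that("gaussian smoothing honors the FWHM-to-sigma conversion", {
  expect_equal(length(dcpredict:::gaussian_kernel_1d(0)), 1)
  # sigma for 6 mm FWHM on 3 mm voxels is 0.84932 voxels
  sigma <- 6 / (3 * 2 * sqrt(2 * log(2)))
  expect_equal(sigma, 0.8493218, tolerance = 1e-6)
  k <- dcpredict:::gaussian_kernel_1d(sigma)
  x <- -((length(k) - 1) / 2):((length(k) - 1) / 2)
  expect_equal(k, exp(-x^2 / (2 * sigma^2)) / sum(exp(-x^2 / (2 * sigma^2))))

  set.seed(1)
  vol <- array(rnorm(6^3), c(6, 6, 6))
  expect_identical(gaussian_smooth(vol, 0), vol)
  const <- array(3.7, c(5, 5, 5))
  expect_equal(gaussian_smooth(const, 6), const, tolerance = 1e-12)
  expect_error(gaussian_smooth(vol, -1), "fwhm")
})

test_that("compute_dc_map is invariant to voxel order and amplitude", {
  b <- tiny_bold(t = 40, dims = c(4, 4, 4), seed = 6)
  dc <- compute_dc_map(b)
  expect_equal(dc$n_voxels, 64)
  # doubling all amplitudes leaves raw degrees untouched
  b2 <- b; b2$data <- 2 * b$data
  expect_equal(compute_dc_map(b2)$raw_degree, dc$raw_degree)
  # permuting voxel order and undoing it reproduces the degrees
  set.seed(8)
  idx <- which(b$mask)
  perm <- sample(idx)
  mat <- matrix(b$data, 64, 40)
  mat_p <- mat; mat_p[idx, ] <- mat[perm, ]
  bp <- b; bp$data <- array(mat_p, dim(b$data))
  deg_p <- compute_dc_map(bp)$raw_degree
  undone <- deg_p; undone[perm] <- deg_p[idx]
  expect_equal(undone, dc$raw_degree)
})

test_that("planted hubs out-rank background voxels in every subject", {
  co <- make_cohort(cohort_config(n_per_group = 6, grid_dims = c(8, 8, 8),
                                  n_timepoints = 60, hub_loading = 2,
                                  effect_delta = 0, responder_effect = 0,
                                  loading_sd = 0, ar_coefficient = 0.3,
                                  noise_sd = 1, seed = 14))
  for (s in cohort_subset(co, "control", "baseline")) {
    pp <- preprocess_subject(s$bold, s$motion)
    dc <- compute_dc_map(pp$bold)
    expect_gt(mean(dc$raw_degree[co$hub_mask]),
              mean(dc$raw_degree[co$mask & !co$hub_mask]))
  }
})
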