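test_that("discard_initial drops exactly the leading volumes", {
  b <- tiny_bold(t = 210)
  out <- discard_initial(b, 10)
  expect_equal(dim(out$data)[4], 200)
  expect_equal(out$data[, , , 1], b$data[, , , 11])
  expect_identical(discard_initial(b, 0), b)
  expect_error(discard_initial(tiny_bold(t = 10), 10), "discard")
  # T = 11 leaves a single volume, which the container itself rejects later
  one <- discard_initial(tiny_bold(t = 11), 10)
  expect_error(bold_series(one$data), "time points")
})

test_that("framewise displacement matches the hand formula and exclusion rule", {
  t <- 20
  m <- zero_motion(t)
  fd0 <- framewise_displacement(m)
  expect_equal(fd0$fd_series, rep(0, t - 1))
  expect_equal(fd0$mean_fd, 0)
  expect_false(fd0$excluded)

  # a single 1 mm x-translation step contributes exactly 1 mm of FD
  m1 <- zero_motion(t); m1[10:t, 1] <- 1
  fd1 <- framewise_displacement(m1)
  expect_equal(fd1$fd_series[9], 1.0)
  expect_equal(sum(fd1$fd_series), 1.0)
  expect_false(fd1$excluded)

  # 0.04 rad = 2.29 deg exceeds the 2-degree rule
  m2 <- zero_motion(t); m2[5, 4] <- 0.04
  expect_true(framewise_displacement(m2)$excluded)
  # 0.03 rad = 1.72 deg does not
  m3 <- zero_motion(t); m3[5, 4] <- 0.03
  expect_false(framewise_displacement(m3)$excluded)

  # rotations are scaled by the head radius
  m4 <- zero_motion(t); m4[2:t, 5] <- 0.01
  expect_equal(framewise_displacement(m4)$fd_series[1], 50 * 0.01)

  expect_error(framewise_displacement(zero_motion(1)), "2 volumes")
})

test_that("FD is invariant to a constant offset on every motion column", {
  set.seed(4)
  m <- matrix(rnorm(30 * 6, sd = 0.1), 30, 6)
  shifted <- sweep(m, 2, c(1, -2, 0.5, 0.01, -0.02, 0.005), "+")
  expect_equal(framewise_displacement(m)$fd_series,
               framewise_displacement(shifted)$fd_series)
})

test_that("confound matrix has the documented 25-column structure", {
  t <- 200
  b <- tiny_bold(t = t)
  m <- matrix(rnorm(t * 6, sd = 0.05), t, 6)
  cf <- build_confounds(m, b)
  expect_equal(dim(cf$matrix), c(t, 25))
  expect_identical(cf$column_names[25], "global_signal")

  # lag, square, and lag-square expansion on a hand case
  m2 <- zero_motion(5); m2[, 1] <- c(1, 2, 3, 4, 5)
  b2 <- tiny_bold(t = 5)
  cf2 <- build_confounds(m2, b2)
  expect_equal(unname(cf2$matrix[1:3, "mp_lag1"]), c(0, 1, 2))
  expect_equal(unname(cf2$matrix[1:3, "mp_sq1"]), c(1, 4, 9))
  expect_equal(unname(cf2$matrix[1:3, "mp_lag_sq1"]), c(0, 1, 4))

  # zero motion: Friston block all zero, global column equals the mask mean
  cf0 <- build_confounds(zero_motion(t), b)
  expect_true(all(cf0$matrix[, 1:24] == 0))
  gs <- apply(b$data, 4, function(v) mean(v[b$mask]))
  expect_equal(unname(cf0$matrix[, 25]), gs)

  expect_error(build_confounds(zero_motion(t - 1), b), "rows")
})

test_that("confound regression matches an explicit normal-equations oracle", {
  set.seed(7)
  t <- 50
  conf <- matrix(rnorm(t * 25), t, 25)
  b <- tiny_bold(t = t, dims = c(3, 3, 3), seed = 8)
  out <- regress_confounds(b, conf)
  X <- cbind(1, conf)
  beta_or <- solve(t(X) %*% X, t(X) %*% matrix(b$data[2, 3, 1, ], ncol = 1))
  res_or <- b$data[2, 3, 1, ] - as.numeric(X %*% beta_or)
  expect_equal(out$data[2, 3, 1, ], res_or, tolerance = 1e-8)

  # residuals are orthogonal to every confound column
  mat <- matrix(out$data, 27, t)
  inner <- abs(mat %*% conf) / (sqrt(rowSums(mat^2)) %o% sqrt(colSums(conf^2)))
  expect_lt(max(inner), 1e-8)
})

test_that("regression handles degenerate designs as specified", {
  t <- 40
  b <- tiny_bold(t = t)
  # a voxel equal to the global signal is annihilated: choosing it as the
  # mean of the other voxels makes it equal the overall mask mean too
  mat <- matrix(b$data, 64, t)
  b$data[1, 1, 1, ] <- colSums(mat[-1, ]) / 63
  cf <- build_confounds(zero_motion(t), b)
  expect_equal(unname(cf$matrix[, "global_signal"]), b$data[1, 1, 1, ])
  out <- regress_confounds(b, cf)
  expect_lt(max(abs(out$data[1, 1, 1, ])), 1e-8)

  # all-constant confounds reduce to intercept-only demeaning
  b2 <- tiny_bold(t = t, seed = 2)
  out2 <- regress_confounds(b2, matrix(1, t, 3))
  expect_equal(out2$data[2, 2, 2, ],
               b2$data[2, 2, 2, ] - mean(b2$data[2, 2, 2, ]))

  # duplicated columns trigger a rank-deficiency error naming columns
  x <- rnorm(t)
  expect_error(regress_confounds(b2, cbind(a = x, b = x)), "collinear")
})

test_that("confound regression is idempotent", {
  set.seed(11)
  t <- 60
  conf <- matrix(rnorm(t * 5), t, 5)
  b <- tiny_bold(t = t, seed = 12)
  once <- regress_confounds(b, conf)
  twice <- regress_confounds(once, conf)
  expect_equal(twice$data, once$data, tolerance = 1e-10)
})

test_that("band-pass keeps in-band sinusoids and rejects out-of-band power", {
  t <- 200; tr <- 2
  dims <- c(2, 2, 2)
  tt <- seq_len(t)
  mk <- function(f) {
    x <- sin(2 * pi * f * tt * tr)
    bold_series(array(rep(x, each = prod(dims)), c(dims, t)), tr_seconds = tr)
  }
  inband <- bandpass(mk(0.04))
  expect_equal(sd(inband$data[1, 1, 1, ]) / sd(mk(0.04)$data[1, 1, 1, ]), 1,
               tolerance = 0.01)
  outband <- bandpass(mk(0.2))
  expect_lt(max(abs(outband$data[1, 1, 1, ])) / max(abs(mk(0.2)$data[1, 1, 1, ])),
            0.01)

  # white noise: out-of-band spectral mass below 1% after filtering
  set.seed(5)
  b <- tiny_bold(t = t, dims = dims, tr = tr, seed = 5)
  filt <- bandpass(b)
  x <- filt$data[1, 1, 1, ]
  spec <- Mod(fft(x))^2
  freqs <- seq(0, t - 1) / (t * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)
  inb <- freqs >= 0.01 & freqs <= 0.08
  expect_lt(sum(spec[!inb]) / sum(spec), 0.01)

  expect_error(bandpass(b, 0.01, 0.3), "Nyquist")
  expect_error(bandpass(b, 0.08, 0.01), "low < high")
})

test_that("band-pass is linear", {
  t <- 120
  b1 <- tiny_bold(t = t, seed = 21)
  b2 <- tiny_bold(t = t, seed = 22)
  comb <- b1; comb$data <- 2 * b1$data - 3 * b2$data
  lhs <- bandpass(comb)$data
  rhs <- 2 * bandpass(b1)$data - 3 * bandpass(b2)$data
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("preprocess_subject chains the stages and reports exclusions", {
  co <- make_cohort(cohort_config(n_per_group = 1, grid_dims = c(6, 6, 6),
                                  n_timepoints = 40, seed = 3))
  s <- co$subjects[[1]]
  pp <- preprocess_subject(s$bold, s$motion)
  expect_equal(dim(pp$bold$data)[4], 40)
  expect_false(pp$excluded)
  # an enormous motion trace trips the 2 mm rule
  bad <- s$motion; bad[25, 1] <- 5
  pp2 <- preprocess_subject(s$bold, bad)
  expect_true(pp2$excluded)
})
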