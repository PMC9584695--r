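separable_data <- function(n_per_class = 6, p = 4, gap = 8, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p, -gap / 2), n_per_class),
             matrix(rnorm(n_per_class * p, gap / 2), n_per_class))
  list(X = X, y = rep(c(FALSE, TRUE), each = n_per_class))
}

test_that("responder labeling applies the strict 50% reduction rule", {
  rec <- function(b, f) list(panss_total_baseline = b, panss_total_followup = f)
  # group-mean trajectory 88.9 -> 53.6 is a 39.7% reduction: nonresponder
  expect_false(label_responders(rec(88.9, 53.6)))
  expect_equal((88.9 - 53.6) / 88.9, 0.397, tolerance = 1e-3)
  expect_false(label_responders(rec(80, 80)))
  expect_true(label_responders(rec(80, 32)))        # 60% reduction
  expect_false(label_responders(rec(80, 40)))       # exactly 50%: strict
  expect_error(label_responders(list(panss_total_baseline = 80)), "follow")
})

test_that("feature extraction is a faithful masked round trip", {
  maps <- quick_dc_maps(make_cohort(cohort_config(
    n_per_group = 2, grid_dims = c(6, 6, 6), n_timepoints = 30, seed = 2)),
    "patient", "baseline", preprocess = FALSE)
  mask <- maps[[1]]$mask
  X <- extract_features(maps, mask)
  expect_equal(dim(X), c(2, sum(mask)))
  idx <- attr(X, "voxel_index")
  vol <- array(0, dim(mask)); vol[idx] <- X[1, ]
  expect_equal(vol[mask], maps[[1]]$smoothed_z[mask])
  expect_error(extract_features(maps, array(FALSE, dim(mask))), "empty")
  expect_error(extract_features(maps, array(TRUE, c(2, 2, 2))), "geometry|mask")
})

test_that("classification metrics follow the confusion-matrix arithmetic", {
  # the unique 19/19 confusion matrix with TP 15, FN 4, TN 17, FP 2
  pred <- c(rep(TRUE, 15), rep(FALSE, 4), rep(FALSE, 17), rep(TRUE, 2))
  labs <- c(rep(TRUE, 19), rep(FALSE, 19))
  m <- classification_metrics(pred, labs)
  expect_equal(round(100 * m$accuracy, 1), 84.2)
  expect_equal(round(100 * m$sensitivity, 1), 78.9)
  expect_equal(round(100 * m$specificity, 1), 89.5)
  all_right <- classification_metrics(labs, labs)
  expect_equal(unlist(all_right[1:3]), c(accuracy = 1, sensitivity = 1,
                                         specificity = 1))
  none <- classification_metrics(rep(FALSE, 38), labs)
  expect_equal(unlist(none[1:3]), c(accuracy = 0.5, sensitivity = 0,
                                    specificity = 1))
  # metric consistency identity
  expect_equal(m$accuracy, (m$sensitivity * 19 + m$specificity * 19) / 38)
})

test_that("AUC equals the Mann-Whitney pair-winning probability", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE))$auc, 0)
  # pos {2, 1}, neg {1.5, 0}: 3 of 4 pairs won
  expect_equal(roc_auc(c(2, 1, 1.5, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  # ties count one half
  expect_equal(roc_auc(c(1, 1), c(TRUE, FALSE))$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "classes")
  # cross-check against an independent ROC implementation
  skip_if_not_installed("pROC")
  set.seed(7)
  d <- rnorm(40); l <- rbinom(40, 1, 0.5) == 1
  expect_equal(roc_auc(d, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, d, quiet = TRUE,
                                              direction = "<"))))
})

test_that("LOOCV is deterministic and perfect on wide-margin clusters", {
  dat <- separable_data()
  r1 <- loocv_classify(dat$X, dat$y)
  r2 <- loocv_classify(dat$X, dat$y)
  expect_equal(r1$accuracy, 1)
  expect_equal(r1$auc, 1)
  expect_identical(r1$decision_values, r2$decision_values)
  expect_error(loocv_classify(dat$X, rep(TRUE, 12)), "classes")
  # duplicating every feature column leaves the predictions unchanged
  rdup <- loocv_classify(cbind(dat$X, dat$X), dat$y)
  expect_equal(rdup$predicted, r1$predicted)
})

test_that("fast decision values equal predict() on the fitted SVM", {
  set.seed(11)
  X <- matrix(rnorm(30 * 8), 30)
  y <- factor(rep(c("nonresponder", "responder"), 15))
  m <- dcpredict:::fit_linear_svm(X, y, 1)
  pr <- predict(m$fit, X, decision.values = TRUE)
  expect_equal(dcpredict:::svm_decision(m, X),
               m$orient * as.numeric(attr(pr, "decision.values")),
               tolerance = 1e-10)
})

test_that("permutation p follows the add-one estimator and is reproducible", {
  dat <- separable_data(n_per_class = 6, gap = 10, seed = 3)
  cfg <- classifier_config(n_permutations = 99, seed = 5)
  pt <- permutation_test(dat$X, dat$y, cfg)
  expect_equal(pt$p_value,
               (1 + sum(pt$null_accuracies >= pt$observed_accuracy)) / 100)
  expect_lte(pt$p_value, 0.05)
  pt2 <- permutation_test(dat$X, dat$y, cfg)
  expect_identical(pt$p_value, pt2$p_value)
  expect_identical(pt$null_accuracies, pt2$null_accuracies)
  # with the full 1000 permutations and no null reaching the observed
  # accuracy the add-one p equals 1/1001
  expect_equal((1 + 0) / (1 + 1000), 0.000999001)
})

test_that("weight map ranks regions by absolute-weight share summing to 100", {
  set.seed(13)
  n <- 16
  mask <- array(FALSE, c(6, 2, 1)); mask[1:6, 1:2, 1] <- TRUE
  # feature columns follow column-major voxel order: the first 6 linear
  # indices are column 1 of the grid (region 1), the next 6 region 2
  atlas <- array(0L, dim(mask))
  atlas[1:6, 1, 1] <- 1L; atlas[1:6, 2, 1] <- 2L
  y <- rep(c(TRUE, FALSE), each = n / 2)
  # all discriminative signal in region 1; region 2 pure noise
  X <- cbind(matrix(rnorm(n * 6) + 3 * y, n),
             matrix(rnorm(n * 6), n))
  feats <- X; attr(feats, "voxel_index") <- which(mask)
  wm <- build_weight_map(feats, y, mask, classifier_config(), atlas)
  expect_equal(sum(wm$region_table$weight_pct), 100, tolerance = 1e-6)
  expect_equal(wm$region_table$region[1], 1)
  expect_equal(wm$region_table$cluster_size, c(6, 6))
  # mirrored identical signal in two regions gives equal shares
  X2 <- cbind(matrix(rnorm(n * 6) + 2 * y, n))
  X2 <- cbind(X2, X2)
  feats2 <- X2; attr(feats2, "voxel_index") <- which(mask)
  wm2 <- build_weight_map(feats2, y, mask, classifier_config(), atlas)
  expect_equal(wm2$region_table$weight_pct[1], wm2$region_table$weight_pct[2],
               tolerance = 1e-6)
  expect_error(build_weight_map(feats, y, mask, classifier_config(),
                                array(0L, c(2, 2, 2))), "geometry")
})

test_that("permutation p never exceeds 1 and shrinks with accuracy", {
  set.seed(17)
  nulls <- runif(99)
  p_of <- function(obs) (1 + sum(nulls >= obs)) / 100
  accs <- seq(0, 1, by = 0.1)
  ps <- vapply(accs, p_of, numeric(1))
  expect_true(all(ps > 0 & ps <= 1))
  expect_true(all(diff(ps) <= 0))
})
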