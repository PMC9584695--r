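#' Classifier configuration
#'
#' Defaults match the standard treatment-response setup: linear soft-margin
#' SVM with C = 1, leave-one-out cross-validation, 1000 label permutations,
#' responders defined by a strict 50% PANSS-total reduction.
#'
#' @param C Soft-margin parameter.
#' @param n_permutations Label permutations for the significance test.
#' @param seed Integer seed for the permutation draw.
#' @param responder_threshold Fractional PANSS reduction defining response.
#' @param standardize Standardize features (training-fold mean/SD) before
#'   fitting?
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(C = 1, n_permutations = 1000L, seed = 1L,
                              responder_threshold = 0.5, standardize = TRUE) {
  structure(list(C = check_real(C, "C", 0, open_lower = TRUE),
                 n_permutations = check_count(n_permutations, "n_permutations"),
                 seed = check_count(seed, "seed", min = -.Machine$integer.max),
                 responder_threshold = check_real(responder_threshold,
                                                 "responder_threshold", 0, 1,
                                                 TRUE, TRUE),
                 standardize = isTRUE(standardize)),
            class = "classifier_config")
}

#' Responder label from a PANSS trajectory
#'
#' A patient is a responder when the fractional reduction
#' `(baseline - followup) / baseline` of the PANSS total strictly exceeds
#' the threshold (default 50%).
#'
#' @param record List or one-row data frame with `panss_total_baseline` and
#'   `panss_total_followup`.
#' @param threshold Fractional reduction cut point.
#' @return `TRUE` for responder, `FALSE` otherwise.
#' @export
label_responders <- function(record, threshold = 0.5) {
  b <- record$panss_total_baseline
  f <- record$panss_total_followup
  if (is.null(b) || is.null(f) || is.na(b) || is.na(f))
    stop("record needs baseline and follow-up PANSS totals", call. = FALSE)
  if (b <= 0) stop("baseline PANSS total must be positive", call. = FALSE)
  (b - f) / b > threshold
}

#' Extract a subjects-by-voxels feature matrix under a mask
#'
#' Rows are subjects, columns the in-mask voxels of the smoothed z map in
#' fixed column-major voxel order; unmasking a row reproduces the original
#' in-mask values.
#'
#' @param dc_maps List of `dc_map` objects.
#' @param mask A `feature_mask` or 3D logical array.
#' @return Numeric matrix with attribute `voxel_index` (linear indices).
#' @export
extract_features <- function(dc_maps, mask) {
  m <- if (inherits(mask, "feature_mask")) mask$mask else mask
  idx <- mask_indices(m)
  if (length(idx) == 0L) stop("feature mask is empty", call. = FALSE)
  X <- stack_dc_maps(dc_maps, m)
  attr(X, "voxel_index") <- idx
  X
}

as_label_factor <- function(labels) {
  if (is.logical(labels))
    labels <- ifelse(labels, "responder", "nonresponder")
  factor(labels, levels = c("nonresponder", "responder"))
}

# Fit a linear SVM and return signed decision values oriented so that
# positive means "responder" (the positive class). The primal weight
# vector w and offset are extracted once so held-out decision values are a
# single inner product (equivalent to predict(..., decision.values), which
# a unit test asserts).
fit_linear_svm <- function(X, y, C) {
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = C,
                    scale = FALSE, type = "C-classification")
  orient <- if (grepl("^responder", colnames(fit$decision.values)[1])) 1 else -1
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  list(fit = fit, orient = orient, w = w, rho = fit$rho)
}

svm_decision <- function(model, Xnew) {
  model$orient * (as.numeric(Xnew %*% model$w) - model$rho)
}

standardizer <- function(Xtrain) {
  mu <- colMeans(Xtrain)
  s <- apply(Xtrain, 2, stats::sd)
  s[s == 0] <- 1
  function(X) sweep(sweep(X, 2, mu), 2, s, "/")
}

loocv_decisions <- function(X, y, config) {
  n <- nrow(X)
  dec <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    if (nlevels(droplevels(ytr)) < 2L)
      stop("a training fold lost one class; need more subjects", call. = FALSE)
    std <- if (config$standardize) standardizer(Xtr) else identity
    model <- fit_linear_svm(std(Xtr), ytr, config$C)
    dec[i] <- svm_decision(model, std(X[i, , drop = FALSE]))
  }
  dec
}

#' Accuracy, sensitivity, specificity with responders positive
#' @param predictions,labels Logical vectors (or responder/nonresponder
#'   factors) of equal length.
#' @return List with `accuracy`, `sensitivity`, `specificity` and the
#'   confusion counts.
#' @export
classification_metrics <- function(predictions, labels) {
  p <- as_label_factor(predictions) == "responder"
  l <- as_label_factor(labels) == "responder"
  if (length(p) != length(l)) stop("length mismatch", call. = FALSE)
  tp <- sum(p & l); fn <- sum(!p & l); tn <- sum(!p & !l); fp <- sum(p & !l)
  list(accuracy = (tp + tn) / length(l),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Area under the ROC curve from decision values
#'
#' Mann-Whitney formulation: the probability that a random positive
#' (responder) decision value exceeds a random negative one, ties counted
#' one half.
#'
#' @param decision_values Numeric scores, larger meaning more
#'   responder-like.
#' @param labels Logical or responder/nonresponder labels.
#' @return List with `auc` and a data frame `curve` of (fpr, tpr) points.
#' @export
roc_auc <- function(decision_values, labels) {
  l <- as_label_factor(labels) == "responder"
  n_pos <- sum(l); n_neg <- sum(!l)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(decision_values, ties.method = "average")
  auc <- (sum(r[l]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(decision_values), decreasing = TRUE)
  curve <- data.frame(
    fpr = c(0, vapply(thr, function(th) mean(decision_values[!l] >= th),
                      numeric(1))),
    tpr = c(0, vapply(thr, function(th) mean(decision_values[l] >= th),
                      numeric(1))))
  list(auc = auc, curve = curve)
}

#' Leave-one-out SVM classification report
#'
#' Each subject is held out once; a linear SVM (features standardized on
#' the training fold when configured) trained on the rest predicts it.
#' Metrics are computed from the pooled held-out predictions, AUC from the
#' pooled signed decision values. Deterministic given features and labels.
#'
#' @param features n x p numeric matrix.
#' @param labels Logical responder flags (or label factor).
#' @param config A [classifier_config()].
#' @return List of class `classifier_report`.
#' @export
loocv_classify <- function(features, labels, config = classifier_config()) {
  X <- as.matrix(features)
  y <- as_label_factor(labels)
  if (nrow(X) < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  dec <- loocv_decisions(X, y, config)
  pred <- dec > 0
  met <- classification_metrics(pred, y)
  roc <- roc_auc(dec, y)
  structure(list(predicted = pred, decision_values = dec,
                 labels = y == "responder",
                 accuracy = met$accuracy, sensitivity = met$sensitivity,
                 specificity = met$specificity, auc = roc$auc,
                 roc_curve = roc$curve, confusion = met[c("tp", "fn", "tn", "fp")],
                 permutation_p = NA_real_, null_accuracies = NULL,
                 config = config),
            class = "classifier_report")
}

#' Permutation significance of the LOOCV accuracy
#'
#' Re-runs the full leave-one-out procedure under `n_permutations` seeded
#' random label permutations and reports the add-one p value
#' `(1 + #\{null accuracy >= observed\}) / (1 + n_permutations)`.
#'
#' @param features,labels,config As in [loocv_classify()].
#' @param observed_accuracy Optionally reuse an already-computed accuracy.
#' @return List with `p_value`, `null_accuracies`, `observed_accuracy`.
#' @export
permutation_test <- function(features, labels, config = classifier_config(),
                             observed_accuracy = NULL) {
  X <- as.matrix(features)
  y <- as_label_factor(labels)
  if (is.null(observed_accuracy))
    observed_accuracy <- loocv_classify(X, y, config)$accuracy
  set.seed(config$seed)
  nulls <- vapply(seq_len(config$n_permutations), function(b) {
    yp <- y[sample.int(length(y))]
    mean((loocv_decisions(X, yp, config) > 0) == (yp == "responder"))
  }, numeric(1))
  p <- (1 + sum(nulls >= observed_accuracy)) / (1 + config$n_permutations)
  list(p_value = p, null_accuracies = nulls,
       observed_accuracy = observed_accuracy)
}

#' SVM weight map and region contribution ranking
#'
#' Trains one linear SVM on all subjects, back-projects the primal weight
#' vector into the feature-mask volume, and ranks atlas regions by
#' discriminative weight: the region's share of the total absolute weight,
#' in percent (summing to 100 over regions intersecting the mask). Peak
#' coordinates are reported in voxel indices and, when an affine is given,
#' in mm.
#'
#' @param features Matrix from [extract_features()] (carries voxel
#'   indices), or a plain matrix plus `voxel_index`.
#' @param labels Responder flags.
#' @param mask A `feature_mask` or 3D logical array.
#' @param config A [classifier_config()].
#' @param atlas 3D integer array of region labels (0 = unlabeled).
#' @param region_names Optional named translation of atlas labels.
#' @param affine Optional 4x4 voxel-to-mm affine for peak coordinates.
#' @return List of class `weight_map`: `weights` (3D array), `region_table`
#'   (data frame sorted by descending weight share).
#' @export
build_weight_map <- function(features, labels, mask,
                             config = classifier_config(), atlas,
                             region_names = NULL, affine = NULL) {
  m <- if (inherits(mask, "feature_mask")) mask$mask else mask
  idx <- attr(features, "voxel_index") %||% mask_indices(m)
  if (!identical(dim(atlas), dim(m)))
    stop("atlas geometry does not match the mask", call. = FALSE)
  X <- as.matrix(features)
  y <- as_label_factor(labels)
  std <- if (config$standardize) standardizer(X) else identity
  model <- fit_linear_svm(std(X), y, config$C)
  sv <- model$fit
  w <- model$orient * as.numeric(t(sv$coefs) %*% sv$SV)
  wvol <- array(0, dim(m))
  wvol[idx] <- w
  lab <- atlas[idx]
  total <- sum(abs(w[lab > 0]))
  if (total == 0) stop("all SVM weights are zero", call. = FALSE)
  regions <- sort(unique(lab[lab > 0]))
  rows <- lapply(regions, function(rg) {
    sel <- lab == rg
    wr <- abs(w[sel])
    peak_lin <- idx[sel][which.max(wr)]
    pk <- arrayInd(peak_lin, dim(m))
    mm <- if (!is.null(affine)) as.numeric(affine %*% c(pk - 1L, 1))[1:3]
          else rep(NA_real_, 3)
    data.frame(region = rg,
               region_name = if (!is.null(region_names))
                 region_names[[as.character(rg)]] %||% as.character(rg)
                 else as.character(rg),
               cluster_size = sum(sel),
               peak_x = pk[1], peak_y = pk[2], peak_z = pk[3],
               peak_mm_x = mm[1], peak_mm_y = mm[2], peak_mm_z = mm[3],
               weight_pct = 100 * sum(wr) / total,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$weight_pct), ]
  rownames(tab) <- NULL
  structure(list(weights = wvol, region_table = tab), class = "weight_map")
}
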