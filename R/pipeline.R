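pipeline_defaults <- function() {
  list(
    n_discard = 10L,
    low_hz = 0.01, high_hz = 0.08,
    global_signal = TRUE,
    max_translation_mm = 2, max_rotation_deg = 2,
    r_threshold = 0.25, fwhm_mm = 6, binary_degree = TRUE,
    q = 0.05,
    C = 1, n_permutations = 1000L, responder_threshold = 0.5,
    run_permutation = TRUE,
    paired_covariates = TRUE,
    seed = 1L,
    cohort = list()
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Every stage parameter carries its conventional default (discard 10,
#' band 0.01-0.08 Hz, r > 0.25, 6 mm FWHM, q = 0.05, C = 1, 1000
#' permutations, 50% responder threshold). Unknown keys are rejected. The
#' `cohort` entry holds [cohort_config()] overrides for the synthetic
#' cohort.
#'
#' @param ... Overrides of the defaults.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg[names(over)] <- over
  cfg$cohort_config <- do.call(cohort_config,
                               c(cfg$cohort,
                                 if (is.null(cfg$cohort$seed))
                                   list(seed = cfg$seed) else NULL))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file of overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: simulate -> temporal preprocessing with motion exclusion ->
#' degree-centrality maps -> covariate-adjusted group inference (two-sample
#' patients-vs-controls at baseline; paired baseline-vs-follow-up in
#' patients) with BH-FDR feature mask -> leave-one-out SVM
#' responder classification with optional permutation test and weight-map
#' region ranking -> regional delta-DC vs delta-PANSS Pearson correlations
#' with FDR. Deterministic under a fixed config.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optionally reuse an already-simulated `synthetic_cohort`
#'   (partial re-run); must match the config's cohort settings.
#' @param out_dir Optional directory for NIfTI/CSV/JSON outputs.
#' @return List of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  t0 <- Sys.time()
  if (is.null(cohort)) cohort <- make_cohort(config$cohort_config)

  dcp <- dc_params(r_threshold = config$r_threshold, fwhm_mm = config$fwhm_mm,
                   binary_degree = config$binary_degree)

  excluded <- character(0)
  dc_maps <- list()
  mean_fd <- list()
  for (s in cohort$subjects) {
    pp <- preprocess_subject(s$bold, s$motion, n_discard = config$n_discard,
                             low_hz = config$low_hz, high_hz = config$high_hz,
                             global_signal = config$global_signal)
    key <- sprintf("%s.%s", s$subject_id, s$session)
    mean_fd[[key]] <- pp$fd$mean_fd
    if (pp$excluded) {
      excluded <- c(excluded, key)
      next
    }
    dc_maps[[key]] <- compute_dc_map(pp$bold, dcp)
  }
  if (length(excluded))
    message(sprintf("excluded %d subject-session(s) exceeding 2 mm / 2 deg: %s",
                    length(excluded), paste(excluded, collapse = ", ")))

  keys <- names(dc_maps)
  recs <- cohort_records(cohort)
  info <- data.frame(
    subject_id = sub("\\.(baseline|followup)$", "", keys),
    session = sub("^.*\\.", "", keys), stringsAsFactors = FALSE)
  info$group <- recs$group[match(info$subject_id, recs$subject_id)]

  covars <- function(sel_keys) {
    ids <- sub("\\.(baseline|followup)$", "", sel_keys)
    r <- recs[match(ids, recs$subject_id), c("age", "gender", "education")]
    r$mean_fd <- unlist(mean_fd[sel_keys])
    r
  }

  pat_base <- keys[info$group == "patient" & info$session == "baseline"]
  pat_fu <- keys[info$group == "patient" & info$session == "followup"]
  ctl_base <- keys[info$group == "control" & info$session == "baseline"]
  # keep only complete patient pairs for the paired contrast
  paired_ids <- intersect(sub("\\.baseline$", "", pat_base),
                          sub("\\.followup$", "", pat_fu))
  pat_base_p <- paste0(paired_ids, ".baseline")
  pat_fu_p <- paste0(paired_ids, ".followup")

  two_sample <- NULL
  if (length(pat_base) >= 3 && length(ctl_base) >= 3)
    two_sample <- voxelwise_two_sample(
      dc_maps[pat_base], dc_maps[ctl_base],
      covariates = rbind(covars(pat_base), covars(ctl_base)),
      mask = cohort$mask)
  paired <- NULL; fmask <- NULL
  if (length(paired_ids) >= 3) {
    paired <- voxelwise_paired(
      dc_maps[pat_base_p], dc_maps[pat_fu_p],
      covariates = if (config$paired_covariates) covars(pat_base_p) else NULL,
      mask = cohort$mask)
    fmask <- fdr_correct(paired, q = config$q)
  }

  cls_cfg <- classifier_config(C = config$C,
                               n_permutations = config$n_permutations,
                               seed = config$seed,
                               responder_threshold = config$responder_threshold)
  classifier <- NULL; perm <- NULL; wmap <- NULL
  labels <- as.logical(recs$responder[match(paired_ids, recs$subject_id)])
  if (!is.null(fmask) && fmask$n_voxels > 0 && length(paired_ids) >= 4 &&
      length(unique(labels)) == 2L) {
    feats <- extract_features(dc_maps[pat_base_p], fmask)
    classifier <- loocv_classify(feats, labels, cls_cfg)
    if (config$run_permutation) {
      perm <- permutation_test(feats, labels, cls_cfg,
                               observed_accuracy = classifier$accuracy)
      classifier$permutation_p <- perm$p_value
      classifier$null_accuracies <- perm$null_accuracies
    }
    wmap <- build_weight_map(feats, labels, fmask, cls_cfg, cohort$atlas)
  }

  delta_dc <- NULL; delta_panss <- NULL; correlations <- NULL
  if (length(paired_ids) >= 3) {
    delta_dc <- region_delta_table(dc_maps[pat_base_p], dc_maps[pat_fu_p],
                                   cohort$atlas)
    rp <- recs[match(paired_ids, recs$subject_id), ]
    delta_panss <- data.frame(
      positive = rp$panss_pos_baseline - rp$panss_pos_followup,
      negative = rp$panss_neg_baseline - rp$panss_neg_followup,
      general = rp$panss_gen_baseline - rp$panss_gen_followup,
      total = rp$panss_total_baseline - rp$panss_total_followup)
    correlations <- pearson_with_fdr(delta_dc, delta_panss, q = config$q)
  }

  report <- structure(list(
    config = config,
    n_subject_sessions = length(cohort$subjects),
    excluded = excluded,
    exclusion_rule = "realignment parameter exceeded 2 mm or 2 degrees",
    mean_fd = unlist(mean_fd),
    n_mask_voxels = sum(cohort$mask),
    two_sample = two_sample, paired = paired, feature_mask = fmask,
    classifier = classifier, weight_map = wmap,
    delta_dc = delta_dc, delta_panss = delta_panss,
    correlations = correlations,
    metrics = list(
      n_feature_voxels = if (!is.null(fmask)) fmask$n_voxels else 0L,
      accuracy = classifier$accuracy %||% NA_real_,
      sensitivity = classifier$sensitivity %||% NA_real_,
      specificity = classifier$specificity %||% NA_real_,
      auc = classifier$auc %||% NA_real_,
      permutation_p = if (!is.null(perm)) perm$p_value else NA_real_,
      top_region = if (!is.null(wmap)) wmap$region_table$region[1] else NA),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = character(0)), class = "run_report")

  if (!is.null(out_dir)) report <- write_report(report, cohort, out_dir)
  report
}

write_report <- function(report, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wv <- function(x, name) {
    p <- file.path(out_dir, name); write_volume(x, p); c(files, p)
  }
  if (!is.null(report$two_sample))
    files <- wv(report$two_sample$t_map, "two_sample_t.nii.gz")
  if (!is.null(report$paired))
    files <- wv(report$paired$t_map, "paired_t.nii.gz")
  if (!is.null(report$feature_mask))
    files <- wv(array(as.numeric(report$feature_mask$mask),
                      dim(report$feature_mask$mask)), "feature_mask.nii.gz")
  if (!is.null(report$weight_map)) {
    files <- wv(report$weight_map$weights, "svm_weights.nii.gz")
    p <- file.path(out_dir, "region_table.csv")
    utils::write.csv(report$weight_map$region_table, p, row.names = FALSE)
    files <- c(files, p)
  }
  if (!is.null(report$correlations)) {
    p <- file.path(out_dir, "correlations.csv")
    utils::write.csv(report$correlations, p, row.names = FALSE)
    files <- c(files, p)
  }
  p <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(report$metrics, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, p)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop(sprintf("output registry inconsistent; missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  report$files <- files
  report
}
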