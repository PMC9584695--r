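#' Synthetic-cohort configuration
#'
#' Describes a two-group (patient/control), two-session (baseline/follow-up)
#' BOLD cohort with latent-network connectivity structure and a planted
#' hub-degree group effect. Defaults emulate a first-episode schizophrenia
#' treatment study: 38 subjects per group, 120 retained volumes at TR 2 s on
#' a 3 mm isotropic grid, and a responder fraction of one half (19/19).
#'
#' The signal model: every in-mask voxel is a weighted sum of shared latent
#' Gaussian AR(1) signals plus independent AR(1) noise. Non-hub voxels load
#' on a single latent with weight 1 (community structure); hub voxels load
#' on every latent with per-latent weight `hub_loading` in a fixed
#' balanced sign pattern, which connects them to every community and gives
#' them genuinely higher graph degree. The useful per-latent loading range
#' is about 0.25-0.9: below it hubs blend into the background, above it the
#' hub-community correlation saturates. Patients at baseline carry hub
#' loading `hub_loading + effect_delta`, renormalizing to `hub_loading` at
#' follow-up; controls sit at `hub_loading` throughout. Treatment response
#' is encoded as a spatial pattern, not a mean shift: every patient carries
#' an antisymmetric redistribution of baseline hub loading over two small
#' blocks at opposite ends of the hub region (magnitude
#' `responder_effect`), and its sign distinguishes responders from
#' nonresponders. Group means and region means are untouched, so the
#' univariate contrasts stay homogeneous while the multivariate classifier
#' has a genuine pattern to learn.
#'
#' @param n_per_group Subjects per group.
#' @param grid_dims Length-3 integer vector of voxels per axis.
#' @param n_timepoints Retained volumes after discarding the first 10 (the
#'   generator emits `n_timepoints + 10` so the discard step is exercised).
#' @param tr_seconds Repetition time in seconds.
#' @param n_latents Number of shared latent signals (communities).
#' @param hub_fraction Fraction of in-mask voxels planted as hubs.
#' @param hub_loading Per-latent connectivity loading of hub voxels.
#' @param effect_delta Extra baseline hub loading in patients (renormalized
#'   away at follow-up).
#' @param responder_effect Magnitude of the antisymmetric baseline
#'   hub-loading redistribution whose sign encodes treatment response; 0
#'   means response is unrelated to centrality.
#' @param loading_sd Between-subject SD of the patient baseline hub-loading
#'   increment (subject heterogeneity).
#' @param symptom_coupling Correlation between the subject-level hub-loading
#'   change and the positive-symptom improvement; 0 disables the coupling
#'   (see [simulate_panss()]).
#' @param ar_latent AR(1) coefficient of the latent signals. The default
#'   0.8 concentrates their power at low frequencies (mimicking slow
#'   hemodynamic fluctuations that the 0.01-0.08 Hz band retains).
#' @param ar_coefficient AR(1) coefficient of the voxel noise (broadband
#'   for small values, so band-pass filtering suppresses most of it).
#' @param noise_sd Marginal SD of the voxel noise.
#' @param responder_fraction Fraction of patients labeled responders.
#' @param motion_sd_mm Random-walk step SD of the simulated motion trace.
#' @param controls_followup Also simulate a follow-up session for controls?
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   bit for bit.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 38L,
                          grid_dims = c(12L, 12L, 12L),
                          n_timepoints = 120L,
                          tr_seconds = 2,
                          n_latents = 6L,
                          hub_fraction = 0.05,
                          hub_loading = 0.25,
                          effect_delta = 0.4,
                          responder_effect = 0.2,
                          loading_sd = 0.1,
                          symptom_coupling = 0,
                          ar_latent = 0.8,
                          ar_coefficient = 0.3,
                          noise_sd = 1,
                          responder_fraction = 0.5,
                          motion_sd_mm = 0.02,
                          controls_followup = FALSE,
                          seed = 1L) {
  cfg <- list(
    n_per_group = check_count(n_per_group, "n_per_group"),
    grid_dims = vapply(seq_len(3), function(i)
      check_count(grid_dims[i], "grid_dims", min = 2L), integer(1)),
    n_timepoints = check_count(n_timepoints, "n_timepoints", min = 10L),
    tr_seconds = check_real(tr_seconds, "tr_seconds", 0, open_lower = TRUE),
    n_latents = check_count(n_latents, "n_latents"),
    hub_fraction = check_real(hub_fraction, "hub_fraction", 0, 1, TRUE, TRUE),
    hub_loading = check_real(hub_loading, "hub_loading", 0),
    effect_delta = check_real(effect_delta, "effect_delta"),
    responder_effect = check_real(responder_effect, "responder_effect"),
    loading_sd = check_real(loading_sd, "loading_sd", 0),
    symptom_coupling = check_real(symptom_coupling, "symptom_coupling", -1, 1),
    ar_latent = check_real(ar_latent, "ar_latent", 0, 1, open_upper = TRUE),
    ar_coefficient = check_real(ar_coefficient, "ar_coefficient", 0, 1,
                                open_upper = TRUE),
    noise_sd = check_real(noise_sd, "noise_sd", 0, open_lower = TRUE),
    responder_fraction = check_real(responder_fraction, "responder_fraction",
                                    0, 1),
    motion_sd_mm = check_real(motion_sd_mm, "motion_sd_mm", 0),
    controls_followup = isTRUE(controls_followup),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (length(grid_dims) != 3L) stop_field("grid_dims", "must have length 3")
  mask <- ellipsoid_mask(cfg$grid_dims)
  if (cfg$hub_fraction * sum(mask) < 1)
    stop_field("hub_fraction", "must select at least one in-mask voxel")
  structure(cfg, class = "cohort_config")
}

# Brain-like ellipsoid mask inscribed in the grid.
ellipsoid_mask <- function(dims) {
  ctr <- (dims + 1) / 2
  rad <- dims / 2
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  inside <- ((g$x - ctr[1]) / rad[1])^2 + ((g$y - ctr[2]) / rad[2])^2 +
    ((g$z - ctr[3]) / rad[3])^2 <= 1
  array(inside, dims)
}

# Hub region: the n nearest in-mask voxels to an off-center seed point
# (contiguous ball, deterministic).
hub_region <- function(mask, n_hub) {
  dims <- dim(mask)
  seed_pt <- (dims + 1) / 2 + dims / 6
  idx <- mask_indices(mask)
  co <- arrayInd(idx, dims)
  d2 <- (co[, 1] - seed_pt[1])^2 + (co[, 2] - seed_pt[2])^2 +
    (co[, 3] - seed_pt[3])^2
  hub_idx <- idx[order(d2)[seq_len(n_hub)]]
  hubs <- array(FALSE, dims)
  hubs[hub_idx] <- TRUE
  hubs
}

# Ground-truth region labels: 1 = planted hub region, 2..9 = octants of the
# remaining mask around the grid center.
cohort_atlas <- function(mask, hubs) {
  dims <- dim(mask)
  ctr <- (dims + 1) / 2
  idx <- mask_indices(mask)
  co <- arrayInd(idx, dims)
  oct <- 1L + (co[, 1] > ctr[1]) + 2L * (co[, 2] > ctr[2]) +
    4L * (co[, 3] > ctr[3])
  atlas <- array(0L, dims)
  atlas[idx] <- oct + 1L
  atlas[hubs] <- 1L
  atlas
}

# T x m matrix of stationary AR(1) series with unit marginal variance.
ar1_series <- function(nt, m, ar) {
  innov_sd <- sqrt(1 - ar^2)
  x <- matrix(0, nt, m)
  x[1, ] <- stats::rnorm(m)
  if (nt > 1) for (t in 2:nt)
    x[t, ] <- ar * x[t - 1, ] + innov_sd * stats::rnorm(m)
  x
}

#' Simulate a random-walk head-motion trace
#'
#' Six columns: three translations (mm) and three rotations (radians), each
#' an independent Gaussian random walk. Rotation steps are scaled by 1/50 so
#' their frame-wise-displacement contribution (on a 50 mm sphere) matches
#' the translations.
#'
#' @param n_vols Number of volumes (rows); at least 2.
#' @param motion_sd_mm Step standard deviation in mm; 0 gives an all-zero
#'   trace.
#' @param seed Integer seed.
#' @return `n_vols` x 6 numeric matrix.
#' @export
simulate_motion <- function(n_vols, motion_sd_mm, seed = 1L) {
  n_vols <- check_count(n_vols, "n_vols", min = 2L)
  check_real(motion_sd_mm, "motion_sd_mm", 0)
  set.seed(seed)
  steps <- matrix(stats::rnorm(n_vols * 6, sd = motion_sd_mm), n_vols, 6)
  steps[, 4:6] <- steps[, 4:6] / 50
  steps[1, ] <- 0
  apply(steps, 2, cumsum)
}

#' Simulate a PANSS trajectory for one patient
#'
#' Baseline subscale scores are drawn near the typical first-episode ranges
#' (positive 7-31, negative 7-34, general 30-64; total constrained to
#' 63-124); the follow-up total is set so that the percent reduction
#' `(baseline - followup)/baseline` strictly exceeds 50% if and only if
#' `responder` is set. When `delta_positive` is supplied (symptom-coupling
#' mode) the follow-up positive score is driven by it instead and the
#' responder contract no longer binds.
#'
#' @param group Must be `"patient"`; controls carry no PANSS trajectory.
#' @param responder Logical flag to plant.
#' @param seed Integer seed.
#' @param delta_positive Optional planted positive-score improvement.
#' @return List with age/education placeholders absent: subscale scores at
#'   baseline and follow-up plus totals.
#' @export
simulate_panss <- function(group, responder, seed = 1L,
                           delta_positive = NULL) {
  if (!identical(group, "patient"))
    stop("controls have no PANSS trajectory", call. = FALSE)
  set.seed(seed)
  floors <- c(pos = 7, neg = 7, gen = 16)
  repeat {
    # coupling mode narrows the baseline positive score so the planted
    # improvement rarely collides with the subscale floor
    pos <- if (is.null(delta_positive))
      round(min(max(stats::rnorm(1, 22.7, 4.7), 7), 31))
    else round(min(max(stats::rnorm(1, 23, 3), 16), 31))
    neg <- round(min(max(stats::rnorm(1, 21.3, 6.4), 7), 34))
    gen <- round(min(max(stats::rnorm(1, 44.5, 8.4), 30), 64))
    total <- pos + neg + gen
    if (total >= 63 && total <= 124) break
  }
  red <- if (responder) stats::runif(1, 0.55, 0.72) else stats::runif(1, 0.08, 0.45)
  target <- total * (1 - red)
  s <- max(0, (target - 30) / (total - 30))
  fu <- floors + (c(pos, neg, gen) - floors) * s
  fu <- round(fu)
  if (!is.null(delta_positive))
    fu["pos"] <- round(min(max(pos - delta_positive, 7), 31))
  fu_total <- sum(fu)
  if (is.null(delta_positive)) {
    # rounding may flip the strict >50% rule; nudge the general score back
    for (i in 1:5) {
      is_resp <- (total - fu_total) / total > 0.5
      if (is_resp == responder) break
      fu["gen"] <- max(floors["gen"], fu["gen"] + if (responder) -1 else 1)
      fu_total <- sum(fu)
    }
  }
  list(panss_pos_baseline = pos, panss_neg_baseline = neg,
       panss_gen_baseline = gen, panss_total_baseline = total,
       panss_pos_followup = unname(fu["pos"]),
       panss_neg_followup = unname(fu["neg"]),
       panss_gen_followup = unname(fu["gen"]),
       panss_total_followup = unname(fu_total))
}

simulate_bold_session <- function(cfg, loadings, hubs, mask, seed) {
  set.seed(seed)
  nt <- cfg$n_timepoints + 10L
  idx <- mask_indices(mask)
  nv <- length(idx)
  latents <- ar1_series(nt, cfg$n_latents, cfg$ar_latent)
  signal <- latents %*% t(loadings)                       # T x V
  noise <- cfg$noise_sd * ar1_series(nt, nv, cfg$ar_coefficient)
  dat <- array(0, c(cfg$grid_dims, nt))
  flat <- matrix(0, prod(cfg$grid_dims), nt)
  flat[idx, ] <- t(signal + noise)
  dat[] <- flat
  bold_series(dat, voxel_size_mm = c(3, 3, 3), tr_seconds = cfg$tr_seconds,
              mask = mask)
}

# Fixed per-hub random-sign patterns over the latents (the cohort's
# "anatomy"): each hub voxel carries its own balanced +/- pattern, drawn
# once per cohort. Sign balance keeps hub signals near-orthogonal to the
# global mean (so hub degree survives global-signal regression), and
# pattern diversity decorrelates degree-estimation noise across hubs.
hub_sign_patterns <- function(n_hub, k, seed) {
  set.seed(seed)
  base <- rep_len(c(1, -1), k)
  t(vapply(seq_len(n_hub), function(i) base[sample.int(k)], numeric(k)))
}

# V x K loading matrix: non-hub voxels load on one latent (round-robin
# communities) with weight 1; hub voxels load on every latent with
# per-latent weight `hub_strength` (scalar, or one value per hub voxel)
# times their fixed sign pattern.
build_loadings <- function(cfg, mask, hubs, hub_strength, patterns) {
  idx <- mask_indices(mask)
  nv <- length(idx)
  k <- cfg$n_latents
  is_hub <- hubs[idx]
  L <- matrix(0, nv, k)
  community <- rep_len(seq_len(k), sum(!is_hub))
  L[cbind(which(!is_hub), community)] <- 1
  L[is_hub, ] <- pmax(0, hub_strength) * patterns
  L
}

# Responder signature carrier: +1 / -1 on two blocks (one quarter of
# the hub region each) at opposite ends of the hub region's longest axis,
# 0 elsewhere. The spatial separation keeps Gaussian smoothing from
# cancelling the antisymmetric pattern, and the untouched 3/4 of the hub
# region preserves the homogeneous group contrast.
hub_signature <- function(hubs) {
  idx <- which(hubs)
  co <- arrayInd(idx, dim(hubs))
  ax <- which.max(apply(co, 2, function(x) diff(range(x))))
  ord <- order(co[, ax], idx)
  n <- length(idx)
  blk <- max(1L, ceiling(n / 4))
  sig <- numeric(n)
  sig[ord[seq_len(blk)]] <- 1
  sig[ord[(n - blk + 1L):n]] <- -1
  sig
}

#' Generate the full synthetic cohort
#'
#' Produces one entry per subject-session: patients at baseline and
#' follow-up, controls at baseline (and follow-up when configured). Each
#' entry carries the BOLD series (including the 10 to-be-discarded leading
#' volumes), the motion trace, and the subject record. The returned object
#' also carries the ground-truth hub mask and a region-label atlas
#' (region 1 is the planted hub region).
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `subjects`, `mask`,
#'   `hub_mask`, `atlas`, `config`.
#' @export
make_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  cfg <- config
  mask <- ellipsoid_mask(cfg$grid_dims)
  n_hub <- max(1L, round(cfg$hub_fraction * sum(mask)))
  hubs <- hub_region(mask, n_hub)
  atlas <- cohort_atlas(mask, hubs)
  patterns <- hub_sign_patterns(n_hub, cfg$n_latents, cfg$seed)
  signature <- hub_signature(hubs)
  nt_full <- cfg$n_timepoints + 10L

  set.seed(cfg$seed)
  n <- cfg$n_per_group
  n_resp <- round(cfg$responder_fraction * n)
  responder <- rep(FALSE, n)
  responder[sample.int(n, n_resp)] <- TRUE
  u <- stats::rnorm(n)                      # subject heterogeneity (patients)
  eps <- stats::rnorm(n)
  rho <- cfg$symptom_coupling
  delta_pos <- 9 + 3 * (rho * u + sqrt(max(0, 1 - rho^2)) * eps)

  demo <- function(group) {
    if (group == "patient")
      list(age = round(min(max(stats::rnorm(1, 24.1, 8.6), 16), 59)),
           gender = stats::rbinom(1, 1, 21 / 38),
           education = round(min(max(stats::rnorm(1, 12.2, 3.1), 4), 19)))
    else
      list(age = round(min(max(stats::rnorm(1, 24.5, 8.3), 17), 58)),
           gender = stats::rbinom(1, 1, 21 / 38),
           education = round(min(max(stats::rnorm(1, 14.1, 3.0), 7), 20)))
  }

  subjects <- list()
  seed_at <- cfg$seed
  next_seed <- function() {
    seed_at <<- seed_at + 1L
    seed_at %% .Machine$integer.max
  }

  for (i in seq_len(n)) {
    id <- sprintf("patient_%02d", i)
    d <- demo("patient")
    panss <- simulate_panss("patient", responder[i], seed = next_seed(),
                            delta_positive = if (rho != 0) delta_pos[i] else NULL)
    rec <- c(list(subject_id = id, group = "patient"), d, panss)
    rec$responder <- label_responders(rec)
    base_strength <- cfg$hub_loading + cfg$effect_delta + cfg$loading_sd * u[i] +
      cfg$responder_effect * signature * (if (responder[i]) 1 else -1)
    for (ses in c("baseline", "followup")) {
      strength <- if (ses == "baseline") base_strength else cfg$hub_loading
      loadings <- build_loadings(cfg, mask, hubs, strength, patterns)
      bold <- simulate_bold_session(cfg, loadings, hubs, mask,
                                    seed = next_seed())
      motion <- simulate_motion(nt_full, cfg$motion_sd_mm, seed = next_seed())
      subjects[[length(subjects) + 1L]] <-
        list(subject_id = id, group = "patient", session = ses,
             bold = bold, motion = motion, record = rec)
    }
  }

  loadings_ctl <- build_loadings(cfg, mask, hubs, cfg$hub_loading, patterns)
  for (i in seq_len(n)) {
    id <- sprintf("control_%02d", i)
    d <- demo("control")
    rec <- c(list(subject_id = id, group = "control"), d,
             list(responder = NA))
    sessions <- if (cfg$controls_followup) c("baseline", "followup") else "baseline"
    for (ses in sessions) {
      bold <- simulate_bold_session(cfg, loadings_ctl, hubs, mask,
                                    seed = next_seed())
      motion <- simulate_motion(nt_full, cfg$motion_sd_mm, seed = next_seed())
      subjects[[length(subjects) + 1L]] <-
        list(subject_id = id, group = "control", session = ses,
             bold = bold, motion = motion, record = rec)
    }
  }

  structure(list(subjects = subjects, mask = mask, hub_mask = hubs,
                 atlas = atlas, config = cfg),
            class = "synthetic_cohort")
}

#' Select cohort subject-sessions
#' @param cohort A `synthetic_cohort`.
#' @param group,session Optional filters.
#' @return List of subject-session entries.
#' @export
cohort_subset <- function(cohort, group = NULL, session = NULL) {
  keep <- vapply(cohort$subjects, function(s) {
    (is.null(group) || s$group == group) &&
      (is.null(session) || s$session == session)
  }, logical(1))
  cohort$subjects[keep]
}

#' Subject table of a cohort as a data frame
#' @param cohort A `synthetic_cohort`.
#' @return One row per subject with demographics and PANSS columns.
#' @export
cohort_records <- function(cohort) {
  ids <- vapply(cohort$subjects, `[[`, "", "subject_id")
  first <- !duplicated(ids)
  recs <- lapply(cohort$subjects[first], `[[`, "record")
  cols <- c("subject_id", "group", "age", "gender", "education",
            "panss_pos_baseline", "panss_neg_baseline", "panss_gen_baseline",
            "panss_total_baseline", "panss_pos_followup",
            "panss_neg_followup", "panss_gen_followup",
            "panss_total_followup", "responder")
  do.call(rbind, lapply(recs, function(r) {
    row <- lapply(cols, function(cl) r[[cl]] %||% NA)
    names(row) <- cols
    as.data.frame(row, stringsAsFactors = FALSE)
  }))
}
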