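#' Per-subject regional degree-centrality change
#'
#' For each labeled region, the mean over region voxels of
#' (baseline smoothed z minus follow-up smoothed z) for one subject.
#'
#' @param dc_baseline,dc_followup `dc_map` objects for the two sessions.
#' @param regions 3D integer label volume (0 = unlabeled); only labels with
#'   at least one voxel occur by construction, an empty requested label is
#'   an error.
#' @param region_ids Optional subset of labels to extract.
#' @return Named numeric vector of mean delta-DC per region.
#' @export
region_delta <- function(dc_baseline, dc_followup, regions,
                         region_ids = NULL) {
  if (!identical(dim(dc_baseline$smoothed_z), dim(regions)) ||
      !identical(dim(dc_followup$smoothed_z), dim(regions)))
    stop("map and region geometry differ", call. = FALSE)
  delta <- dc_baseline$smoothed_z - dc_followup$smoothed_z
  ids <- region_ids %||% sort(unique(regions[regions > 0]))
  out <- vapply(ids, function(rg) {
    sel <- regions == rg
    if (!any(sel)) stop(sprintf("region %s is empty", rg), call. = FALSE)
    mean(delta[sel])
  }, numeric(1))
  names(out) <- as.character(ids)
  out
}

#' Build the subjects x regions delta-DC table for a patient set
#' @param baseline_maps,followup_maps Paired lists of `dc_map` objects.
#' @param regions 3D integer label volume.
#' @param region_ids Optional label subset.
#' @return Data frame, one row per subject, one column per region.
#' @export
region_delta_table <- function(baseline_maps, followup_maps, regions,
                               region_ids = NULL) {
  if (length(baseline_maps) != length(followup_maps))
    stop("paired map lists must have equal length", call. = FALSE)
  rows <- mapply(function(b, f) region_delta(b, f, regions, region_ids),
                 baseline_maps, followup_maps, SIMPLIFY = FALSE)
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Pearson correlations of regional delta-DC with symptom change, FDR-corrected
#'
#' Correlates each region's delta-DC column with each symptom-change column
#' (two-sided p values) and applies one Benjamini-Hochberg pass over the
#' whole region x subscale family. Pairs with zero variance in either
#' variable are flagged undefined and excluded from the FDR family.
#'
#' @param delta_dc Data frame / matrix, subjects x regions.
#' @param delta_panss Data frame / matrix, subjects x subscales
#'   (baseline minus follow-up, improvement positive).
#' @param q FDR level.
#' @return Data frame with region, subscale, r, p, q_significant, defined.
#' @export
pearson_with_fdr <- function(delta_dc, delta_panss, q = 0.05) {
  dd <- as.data.frame(delta_dc)
  dp <- as.data.frame(delta_panss)
  if (nrow(dd) != nrow(dp)) stop("subject rows differ", call. = FALSE)
  if (nrow(dd) < 3L) stop("need at least 3 subjects", call. = FALSE)
  grid <- expand.grid(region = names(dd), subscale = names(dp),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    x <- dd[[grid$region[i]]]; y <- dp[[grid$subscale[i]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(grid[i, ], r = NA_real_, p = NA_real_,
                        defined = FALSE))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(grid[i, ], r = unname(ct$estimate), p = ct$p.value,
               defined = TRUE)
  }))
  res$q_significant <- FALSE
  if (any(res$defined)) {
    padj <- stats::p.adjust(res$p[res$defined], method = "BH")
    res$q_significant[res$defined] <- padj <= q
  }
  rownames(res) <- NULL
  res
}
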