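#' Read a NIfTI volume
#'
#' 3D files come back as plain arrays; 4D files as a [bold_series()] whose
#' TR is taken from the header pixdim (overridable).
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param mask Optional 3D logical array for 4D reads.
#' @param tr_seconds Optional TR override.
#' @return 3D array or `bold_series`.
#' @export
read_volume <- function(path, mask = NULL, tr_seconds = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot read '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  d <- dim(img)
  px <- RNifti::pixdim(img)
  if (length(d) == 3L) return(array(as.numeric(img), d))
  if (length(d) != 4L) stop(sprintf("'%s' is not 3D or 4D", path), call. = FALSE)
  tr <- tr_seconds %||% (if (length(px) >= 4 && px[4] > 0) px[4] else 2)
  if (!is.null(mask) && !identical(dim(mask), d[1:3]))
    stop(sprintf("mask geometry does not match '%s'", path), call. = FALSE)
  bold_series(array(as.numeric(img), d), voxel_size_mm = px[1:3],
              tr_seconds = tr, mask = mask)
}

#' Write a 3D/4D array or bold_series as NIfTI-1
#' @param x 3D array, 4D array, or `bold_series`.
#' @param path Output file.
#' @param voxel_size_mm Voxel sizes for plain arrays.
#' @param tr_seconds TR recorded in the header for 4D data.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = c(3, 3, 3),
                         tr_seconds = NULL) {
  if (inherits(x, "bold_series")) {
    voxel_size_mm <- x$voxel_size_mm
    tr_seconds <- x$tr_seconds
    x <- x$data
  }
  img <- RNifti::asNifti(x)
  pd <- c(voxel_size_mm, tr_seconds %||% 1)[seq_along(dim(x))]
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a motion-parameter matrix as whitespace-delimited text
#' @param motion T x 6 matrix.
#' @param path Output file.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(as_motion(motion), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a 6-column motion-parameter text file
#' @param path Whitespace-delimited file, one row per volume.
#' @return T x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  unname(as_motion(as.matrix(utils::read.table(path))))
}

subject_table_columns <- c(
  "subject_id", "group", "age", "gender", "education",
  "panss_pos_baseline", "panss_neg_baseline", "panss_gen_baseline",
  "panss_total_baseline", "panss_pos_followup", "panss_neg_followup",
  "panss_gen_followup", "panss_total_followup")

#' Read and validate a subject table
#'
#' Requires the demographic columns for all rows and PANSS columns for
#' patients; derives the responder label for patients with a follow-up
#' total. PANSS totals below the scale floor of 30 and duplicate subject
#' ids are rejected.
#'
#' @param path CSV file.
#' @param responder_threshold Passed to [label_responders()].
#' @return Data frame with a derived `responder` column.
#' @export
read_subject_table <- function(path, responder_threshold = 0.5) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", "group", "age", "gender", "education"),
                     names(tab))
  if (length(missing))
    stop(sprintf("subject table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id in subject table", call. = FALSE)
  if (!all(tab$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'", call. = FALSE)
  panss_cols <- grep("^panss_", subject_table_columns, value = TRUE)
  for (cl in intersect(panss_cols, names(tab))) {
    bad <- which(tab$group == "patient" & !is.na(tab[[cl]]) &
                   !is.finite(suppressWarnings(as.numeric(tab[[cl]]))))
    if (length(bad))
      stop(sprintf("non-numeric PANSS in row %d, column %s", bad[1], cl),
           call. = FALSE)
  }
  for (cl in c("panss_total_baseline", "panss_total_followup")) {
    if (!cl %in% names(tab)) next
    bad <- which(tab$group == "patient" & !is.na(tab[[cl]]) & tab[[cl]] < 30)
    if (length(bad))
      stop(sprintf("PANSS total below the scale floor of 30 in row %d (%s)",
                   bad[1], cl), call. = FALSE)
  }
  tab$responder <- NA
  ok <- tab$group == "patient" &
    !is.na(tab[["panss_total_baseline"]] %||% NA) &
    !is.na(tab[["panss_total_followup"]] %||% NA)
  if (any(ok))
    tab$responder[ok] <- (tab$panss_total_baseline[ok] -
                            tab$panss_total_followup[ok]) /
      tab$panss_total_baseline[ok] > responder_threshold
  tab
}

#' Write a cohort to disk (NIfTI volumes, motion text, subject CSV)
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisible list of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (s in cohort$subjects) {
    stem <- file.path(dir, sprintf("%s_%s", s$subject_id, s$session))
    paths[[length(paths) + 1L]] <- write_volume(s$bold, paste0(stem, ".nii.gz"))
    paths[[length(paths) + 1L]] <- write_motion(s$motion, paste0(stem, "_rp.txt"))
  }
  mk <- file.path(dir, "mask.nii.gz")
  write_volume(array(as.numeric(cohort$mask), dim(cohort$mask)), mk)
  at <- file.path(dir, "atlas.nii.gz")
  write_volume(array(as.numeric(cohort$atlas), dim(cohort$atlas)), at)
  tab <- cohort_records(cohort)
  csv <- file.path(dir, "subjects.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  invisible(c(paths, mk, at, csv))
}
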