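# Small builders shared across tests. Everything is generated in code;
# nothing is read from disk.

tiny_bold <- function(t = 40, dims = c(4, 4, 4), tr = 2, seed = 1,
                      mask = NULL) {
  set.seed(seed)
  bold_series(array(rnorm(prod(dims) * t), c(dims, t)),
              voxel_size_mm = c(3, 3, 3), tr_seconds = tr, mask = mask)
}

zero_motion <- function(t) matrix(0, t, 6)

# Direct all-pairs degree computation, the independent oracle for
# degree_from_timeseries (full correlation matrix, no blocking).
naive_degree <- function(ts, r_threshold = 0.25, binary = TRUE) {
  r <- suppressWarnings(cor(ts))
  r[is.na(r)] <- 0
  diag(r) <- 0
  edge <- r > r_threshold
  if (binary) colSums(edge) else colSums(r * edge)
}

# Literal double loop on cor(x, y), used on very small instances.
pairloop_degree <- function(ts, r_threshold = 0.25) {
  v <- ncol(ts)
  deg <- integer(v)
  for (i in seq_len(v)) for (j in seq_len(v)) {
    if (i != j && cor(ts[, i], ts[, j]) > r_threshold)
      deg[i] <- deg[i] + 1L
  }
  deg
}

quick_dc_maps <- function(cohort, group, session,
                          preprocess = TRUE) {
  lapply(cohort_subset(cohort, group, session), function(s) {
    if (preprocess) {
      pp <- preprocess_subject(s$bold, s$motion)
      compute_dc_map(pp$bold)
    } else {
      compute_dc_map(discard_initial(s$bold))
    }
  })
}

patient_labels <- function(cohort) {
  recs <- cohort_records(cohort)
  as.logical(recs$responder[recs$group == "patient"])
}
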