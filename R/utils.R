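`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_real <- function(x, field, lower = -Inf, upper = Inf,
                       open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be a single finite number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_field(field, sprintf("must lie in %s%g, %g%s",
                              if (open_lower) "(" else "[", lower, upper,
                              if (open_upper) ")" else "]"))
  as.numeric(x)
}

#' In-mask linear voxel indices in fixed column-major order
#' @param mask 3D logical array.
#' @return Integer vector of linear indices.
#' @keywords internal
mask_indices <- function(mask) which(as.logical(mask))
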