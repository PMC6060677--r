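#' Parameters for recursive segment-wise peak alignment
#'
#' @param max_shift_points hard cap on the candidate integer shift (points);
#'   within each segment the search window is additionally limited to 2% of
#'   the segment length, so long segments move coarsely and short segments
#'   finely.
#' @param min_window_points floor of the per-segment search window (points).
#'   Size it to cover the expected peak drift: a window smaller than the
#'   drift cannot correct it at the finest segments.
#' @param min_segment_points segments shorter than twice this are not split
#'   further (>= 8).
#' @param recursion_depth_max maximum recursion depth.
#' @param improvement_min minimum gain in correlation with the reference for
#'   a candidate shift to be accepted (>= 0).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(max_shift_points = 50L,
                             min_window_points = 5L,
                             min_segment_points = 64L,
                             recursion_depth_max = 10L,
                             improvement_min = 0) {
  stopifnot(max_shift_points >= 0, min_window_points >= 1,
            min_segment_points >= 8, recursion_depth_max >= 1,
            improvement_min >= 0)
  structure(list(max_shift_points = as.integer(max_shift_points),
                 min_window_points = as.integer(min_window_points),
                 min_segment_points = as.integer(min_segment_points),
                 recursion_depth_max = as.integer(recursion_depth_max),
                 improvement_min = improvement_min),
            class = "alignment_params")
}

# shift a vector by s points, padding with its own edge values
shift_pad <- function(x, s) {
  n <- length(x)
  if (s == 0) return(x)
  if (abs(s) >= n) return(rep(x[if (s > 0) 1 else n], n))
  if (s > 0) c(rep(x[1], s), x[seq_len(n - s)])
  else c(x[(1 - s):n], rep(x[n], -s))
}

# correlation that tolerates constant vectors (returns 0 rather than NA)
safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

# Best integer shift of `seg` against `ref` within +/- m, ties broken toward
# the smallest |shift| (0 first). Returns the shift and its correlation gain.
best_segment_shift <- function(seg, ref, m, improvement_min) {
  if (m == 0) return(0L)
  shifts <- c(0L, as.integer(rbind(-seq_len(m), seq_len(m))))
  cors <- vapply(shifts, function(s) safe_cor(shift_pad(seg, s), ref),
                 numeric(1))
  best <- which.max(cors)           # first max: prefers 0, then small |s|
  if (shifts[best] != 0L && (cors[best] - cors[1]) >= improvement_min &&
      cors[best] > cors[1]) {
    shifts[best]
  } else 0L
}

align_segment <- function(x, ref, lo, hi, depth, params, log_env) {
  len <- hi - lo + 1L
  m <- min(params$max_shift_points,
           max(params$min_window_points, floor(0.02 * len)))
  m <- min(m, len - 1L)
  seg <- x[lo:hi]
  s <- best_segment_shift(seg, ref[lo:hi], m, params$improvement_min)
  if (s != 0L) {
    seg <- shift_pad(seg, s)
    x[lo:hi] <- seg
  }
  log_env$shifts[[length(log_env$shifts) + 1L]] <-
    c(lo = lo, hi = hi, shift = s, depth = depth)
  if (len >= 2L * params$min_segment_points &&
      depth < params$recursion_depth_max) {
    # split at the minimum-intensity point in the middle third
    third <- len %/% 3L
    win <- (lo + third):(hi - third)
    split <- win[which.min(seg[(third + 1L):(len - third)])]
    if (split > lo && split < hi) {
      x <- align_segment(x, ref, lo, split, depth + 1L, params, log_env)
      x <- align_segment(x, ref, split + 1L, hi, depth + 1L, params, log_env)
    }
  }
  x
}

#' Recursive segment-wise peak alignment (RSPA)
#'
#' Aligns each spectrum to a reference by recursive segmentation: the best
#' integer shift of the whole segment (maximum Pearson correlation with the
#' reference within a window that shrinks with segment length) is applied
#' when it improves the correlation by at least `improvement_min`; the
#' segment is then split at the minimum-intensity point of its middle third
#' and both halves are aligned recursively, until segments reach
#' `min_segment_points` or the depth limit. Points shifted past a segment
#' edge are filled by edge-value padding, so the number of points never
#' changes. Shifts are whole grid points (no sub-grid interpolation), which
#' keeps the procedure exactly reproducible.
#'
#' @param spectra an [nmr_spectra] object.
#' @param reference `"median"` (column-wise median spectrum), `"mean"`, a
#'   sample id, or an external numeric reference spectrum of length
#'   `ncol`. The data-driven references inherit the cohort's consensus peak
#'   positions; an external template pins the target positions exactly.
#' @param params an [alignment_params()] list.
#' @return A list of class `rspa_result`: `spectra` (aligned) and `shifts`,
#'   a tibble with one row per (sample, segment): `sample_id`, `lo`, `hi`
#'   (column indices), `shift` (points), `depth`.
#' @export
rspa_align <- function(spectra, reference = "median",
                       params = alignment_params()) {
  stopifnot(inherits(spectra, "nmr_spectra"),
            inherits(params, "alignment_params"))
  X <- spectra$intensities
  if (params$min_segment_points > ncol(X)) {
    abort("`min_segment_points` exceeds the number of spectral points.")
  }
  if (nrow(X) < 2 && is.character(reference) &&
      reference %in% c("median", "mean")) {
    abort("A summary reference needs >= 2 samples; name a reference sample id.")
  }
  ref <- if (is.numeric(reference)) {
    if (length(reference) != ncol(X)) {
      abort("External reference length must match the number of columns.")
    }
    as.numeric(reference)
  } else if (identical(reference, "median")) {
    apply(X, 2, median)
  } else if (identical(reference, "mean")) {
    colMeans(X)
  } else {
    if (!reference %in% rownames(X)) {
      abort(sprintf("No sample '%s' in the matrix.", reference))
    }
    X[reference, ]
  }
  out <- X
  all_shifts <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    log_env <- new.env(parent = emptyenv())
    log_env$shifts <- list()
    out[i, ] <- align_segment(X[i, ], ref, 1L, ncol(X), 1L, params, log_env)
    rec <- do.call(rbind, log_env$shifts)
    all_shifts[[i]] <- tibble::tibble(
      sample_id = rownames(X)[i],
      lo = as.integer(rec[, "lo"]), hi = as.integer(rec[, "hi"]),
      shift = as.integer(rec[, "shift"]), depth = as.integer(rec[, "depth"]))
  }
  structure(list(
    spectra = nmr_spectra(out, spectra$ppm, sample_ids(spectra)),
    shifts = dplyr::bind_rows(all_shifts)
  ), class = "rspa_result")
}
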