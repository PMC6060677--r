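#' Build a set of ppm regions
#'
#' @param ... length-2 numeric vectors `c(low, high)` in ppm; regions may
#'   overlap (union semantics).
#' @return A tibble of class `region_set` with columns `low_ppm`, `high_ppm`.
#' @examples
#' region_set(c(4.7, 4.9))
#' @export
region_set <- function(...) {
  regs <- list(...)
  if (length(regs) == 1 && is.list(regs[[1]]) && !is.data.frame(regs[[1]])) {
    regs <- regs[[1]]
  }
  out <- purrr::map_dfr(regs, function(r) {
    if (length(r) != 2 || !is.numeric(r)) {
      abort("Each region must be a numeric c(low, high) pair.")
    }
    if (r[1] >= r[2]) abort("Region low bound must be < high bound.")
    tibble::tibble(low_ppm = r[1], high_ppm = r[2])
  })
  class(out) <- c("region_set", class(tibble::tibble()))
  out
}

#' Default excluded region for human urine spectra
#'
#' The residual-water window 4.7-4.9 ppm, removed so imperfect solvent
#' suppression cannot contribute variance.
#' @return A [region_set()].
#' @export
water_region <- function() region_set(c(4.7, 4.9))

#' Drop spectral columns inside ppm regions
#'
#' Removes every column whose ppm falls in the closed union of the given
#' regions; the axis and intensity columns stay aligned and the sample set is
#' unchanged.
#'
#' @param spectra an [nmr_spectra] object.
#' @param regions a [region_set()] (empty set = identity).
#' @return The reduced [nmr_spectra].
#' @export
exclude_regions <- function(spectra, regions) {
  stopifnot(inherits(spectra, "nmr_spectra"))
  if (nrow(regions) == 0) return(spectra)
  drop <- rep(FALSE, length(spectra$ppm))
  for (i in seq_len(nrow(regions))) {
    drop <- drop | (spectra$ppm >= regions$low_ppm[i] &
                    spectra$ppm <= regions$high_ppm[i])
  }
  if (all(drop)) abort("Region set would remove every spectral column.")
  nmr_spectra(spectra$intensities[, !drop, drop = FALSE],
              spectra$ppm[!drop], sample_ids(spectra))
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution: each spectrum is divided by the median, over
#' spectral variables, of its point-wise ratio to a reference spectrum. The
#' default reference is the column-wise median spectrum of all samples.
#' Columns where the reference falls below `eps` times its maximum are
#' treated as signal-free and excluded from the quotient: in baseline- or
#' noise-dominated columns the point-wise ratio carries no dilution
#' information and would otherwise bias the median for sparse spectra.
#'
#' @param spectra an [nmr_spectra] object (>= 2 samples for the median
#'   reference).
#' @param reference `"median"`, a sample id, or an external numeric vector of
#'   length `ncol`.
#' @param eps relative signal floor: reference columns below
#'   `eps * max(reference)` are ignored (default 1%).
#' @return A list of class `pqn_result`: `spectra` (normalized),
#'   `quotients` (named per-sample dilution estimates), `reference`.
#' @examples
#' des <- cohort_design(c(case = 3, village_control = 3), n_points = 300,
#'                      ppm_range = c(2, 4), water_residual = FALSE)
#' coh <- simulate_cohort(des)
#' pq <- pqn_normalize(coh$spectra)
#' pq$quotients
#' @export
pqn_normalize <- function(spectra, reference = "median", eps = 0.01) {
  stopifnot(inherits(spectra, "nmr_spectra"))
  X <- spectra$intensities
  ref <- if (is.numeric(reference)) {
    if (length(reference) != ncol(X)) {
      abort("External reference length must match the number of columns.")
    }
    as.numeric(reference)
  } else if (identical(reference, "median")) {
    if (nrow(X) < 2) abort("Median reference needs >= 2 samples.")
    apply(X, 2, median)
  } else {
    if (!reference %in% rownames(X)) {
      abort(sprintf("No sample '%s' in the matrix.", reference))
    }
    X[reference, ]
  }
  usable <- ref > eps * max(ref)
  if (!any(usable)) abort("Reference spectrum has no usable columns.")
  q <- vapply(seq_len(nrow(X)), function(i) {
    ratios <- X[i, usable] / ref[usable]
    ratios <- ratios[is.finite(ratios)]
    if (!length(ratios)) {
      abort(sprintf("Sample '%s' has no usable columns for PQN.",
                    rownames(X)[i]))
    }
    median(ratios)
  }, numeric(1))
  if (any(q == 0)) {
    abort(sprintf("Zero quotient for sample(s): %s",
                  paste(rownames(X)[q == 0], collapse = ", ")))
  }
  names(q) <- rownames(X)
  structure(list(
    spectra = nmr_spectra(X / q, spectra$ppm, sample_ids(spectra)),
    quotients = q, reference = ref
  ), class = "pqn_result")
}

#' Mean-centre and unit-variance scale spectral columns
#'
#' Columns are centred and divided by their sample SD (n - 1 denominator).
#' Zero-variance columns are dropped and recorded so loadings can be
#' back-transformed onto the original intensity scale.
#'
#' @param x an [nmr_spectra] object or plain matrix (>= 2 rows).
#' @param tol absolute SD below which a column counts as constant.
#' @return A list of class `uv_scaled`: `X` (scaled matrix, kept columns
#'   only) and `state` (list with `column_means`, `column_sds`,
#'   `kept_columns` index vector, and `ppm` of kept columns when available).
#' @export
scale_uv <- function(x, tol = 1e-12) {
  ppm <- NULL
  if (inherits(x, "nmr_spectra")) {
    ppm <- x$ppm
    x <- x$intensities
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("Scaling needs >= 2 samples.")
  ms <- col_means_sds(x)
  kept <- which(ms$sds > tol)
  if (!length(kept)) abort("All columns have zero variance.")
  Xs <- sweep(x[, kept, drop = FALSE], 2, ms$means[kept], "-")
  Xs <- sweep(Xs, 2, ms$sds[kept], "/")
  state <- list(column_means = ms$means, column_sds = ms$sds,
                kept_columns = kept,
                ppm = if (!is.null(ppm)) ppm[kept] else NULL)
  structure(list(X = Xs, state = state), class = "uv_scaled")
}

#' Apply a stored scaling state to new data
#' @param x matrix or [nmr_spectra] with the same columns as the training
#'   data before scaling.
#' @param state the `state` element of a [scale_uv()] result.
#' @return Scaled matrix restricted to the kept columns.
#' @export
apply_scaling <- function(x, state) {
  if (inherits(x, "nmr_spectra")) x <- x$intensities
  x <- as.matrix(x)
  if (ncol(x) != length(state$column_means)) {
    abort("Column count differs from the training scaling state.")
  }
  k <- state$kept_columns
  sweep(sweep(x[, k, drop = FALSE], 2, state$column_means[k], "-"),
        2, state$column_sds[k], "/")
}

#' Invert unit-variance scaling
#' @param Xs scaled matrix (kept columns).
#' @param state the scaling state.
#' @return Matrix on the original intensity scale (kept columns only).
#' @export
unscale_uv <- function(Xs, state) {
  k <- state$kept_columns
  sweep(sweep(as.matrix(Xs), 2, state$column_sds[k], "*"),
        2, state$column_means[k], "+")
}
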