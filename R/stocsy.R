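#' Statistical total correlation spectroscopy (STOCSY)
#'
#' Correlates one spectral variable (the driver) against every variable
#' across samples. Peaks from the same molecule show near-unit correlation
#' with the driver, which is the basis of assignment; the covariance trace
#' coloured by r^2 is the classical STOCSY display.
#'
#' @param spectra an [nmr_spectra] object or plain matrix (>= 3 samples),
#'   typically after normalization/alignment but before scaling.
#' @param driver_ppm chemical shift of the driver peak; the nearest grid
#'   point is used. For a plain matrix, give `driver_index` instead.
#' @param driver_index column index of the driver (overrides `driver_ppm`).
#' @return A tibble of class `stocsy_result`: `variable`, `ppm` (when
#'   known), `r`, `cov`, `r2`; attribute `driver` (index) and `driver_ppm`.
#' @examples
#' des <- cohort_design(c(case = 5, village_control = 5), n_points = 500,
#'                      ppm_range = c(6.5, 8), water_residual = FALSE)
#' coh <- simulate_cohort(des)
#' st <- stocsy(coh$spectra, driver_ppm = 7.84)
#' @export
stocsy <- function(spectra, driver_ppm = NULL, driver_index = NULL) {
  ppm <- NULL
  if (inherits(spectra, "nmr_spectra")) {
    ppm <- spectra$ppm
    X <- spectra$intensities
  } else {
    X <- as.matrix(spectra)
  }
  if (nrow(X) < 3) abort("STOCSY needs >= 3 samples.")
  if (is.null(driver_index)) {
    if (is.null(driver_ppm)) abort("Give `driver_ppm` or `driver_index`.")
    if (is.null(ppm)) abort("No ppm axis; give `driver_index` instead.")
    if (driver_ppm > max(ppm) || driver_ppm < min(ppm)) {
      abort(sprintf("driver_ppm %.3f outside the axis range [%.3f, %.3f].",
                    driver_ppm, min(ppm), max(ppm)))
    }
    driver_index <- ppm_index(ppm, driver_ppm)
  }
  d <- X[, driver_index]
  if (sd(d) == 0) abort("Driver column has zero variance.")
  dc <- d - mean(d)
  Xc <- sweep(X, 2, colMeans(X), "-")
  covv <- drop(crossprod(Xc, dc)) / (nrow(X) - 1)
  sds <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
  r <- covv / (sds * sd(d))
  r[sds == 0] <- 0
  out <- tibble::tibble(
    variable = seq_len(ncol(X)),
    ppm = if (!is.null(ppm)) ppm else NA_real_,
    r = r, cov = covv, r2 = r^2
  )
  attr(out, "driver") <- driver_index
  attr(out, "driver_ppm") <- if (!is.null(ppm)) ppm[driver_index] else NA_real_
  class(out) <- c("stocsy_result", class(tibble::tibble()))
  out
}

#' STOCSY covariance trace coloured by r^2
#' @param object a [stocsy()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot stocsy_result
#' @export
autoplot.stocsy_result <- function(object, ...) {
  has_ppm <- !all(is.na(object$ppm))
  x <- if (has_ppm) "ppm" else "variable"
  p <- ggplot2::ggplot(object, ggplot2::aes(.data[[x]], .data$cov,
                                            colour = .data$r2)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1), name = expression(r^2)) +
    ggplot2::labs(x = if (has_ppm) "Chemical shift (ppm)" else "Variable",
                  y = "Covariance with driver") +
    ggplot2::theme_minimal()
  if (has_ppm) p <- p + ggplot2::scale_x_reverse()
  p
}
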