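#' Construct a spectra matrix
#'
#' Bundles a samples-by-points intensity matrix with its shared chemical-shift
#' axis. The axis is stored in descending ppm order (the NMR plotting
#' convention); an ascending axis is reversed, together with the intensity
#' columns, with a warning. All preprocessing and modelling functions in the
#' package accept and return this container.
#'
#' @param intensities numeric matrix, one row per sample, one column per
#'   chemical-shift grid point. Row names, if present, seed the sample ids.
#' @param ppm numeric vector of chemical shifts (ppm), strictly monotone,
#'   length `ncol(intensities)`.
#' @param sample_ids character vector of unique sample identifiers.
#' @return An object of class `nmr_spectra`: a list with elements
#'   `intensities` (matrix, rownames = sample ids) and `ppm`.
#' @examples
#' sp <- nmr_spectra(matrix(rnorm(6), 2, 3), ppm = c(3, 2, 1))
#' sp
#' @export
nmr_spectra <- function(intensities, ppm,
                        sample_ids = rownames(intensities)) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  ppm <- as.numeric(ppm)
  if (length(ppm) != ncol(intensities)) {
    abort(sprintf("`ppm` has length %d but `intensities` has %d columns.",
                  length(ppm), ncol(intensities)))
  }
  d <- diff(ppm)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    abort("`ppm` must be strictly monotone.")
  }
  if (length(d) && all(d > 0)) {
    warn("`ppm` supplied ascending; reversing to the descending convention.")
    ppm <- rev(ppm)
    intensities <- intensities[, rev(seq_len(ncol(intensities))), drop = FALSE]
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%03d", seq_len(nrow(intensities)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(intensities)) {
    abort("`sample_ids` must have one entry per spectrum.")
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    abort(sprintf("Duplicate sample id(s): %s", paste(dup, collapse = ", ")))
  }
  if (!all(is.finite(intensities))) {
    abort("`intensities` contains non-finite values.")
  }
  rownames(intensities) <- sample_ids
  structure(list(intensities = intensities, ppm = ppm),
            class = "nmr_spectra")
}

#' @export
print.nmr_spectra <- function(x, ...) {
  cat(sprintf("<nmr_spectra> %d spectra x %d points, ppm %.3f..%.3f\n",
              nrow(x$intensities), length(x$ppm),
              max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' @export
dim.nmr_spectra <- function(x) dim(x$intensities)

#' Sample identifiers of a spectra matrix
#' @param x an [nmr_spectra] object.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x$intensities)

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Long-format view of a spectra matrix
#'
#' @param x an [nmr_spectra] object.
#' @param ... unused.
#' @return A tibble with columns `sample_id`, `ppm`, `intensity`, one row per
#'   sample and grid point — convenient for ggplot2 overlays.
#' @method as_tibble nmr_spectra
#' @export
as_tibble.nmr_spectra <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(sample_ids(x), each = length(x$ppm)),
    ppm = rep(x$ppm, times = nrow(x$intensities)),
    intensity = as.vector(t(x$intensities))
  )
}

#' Overlay plot of spectra
#'
#' @param object an [nmr_spectra] object.
#' @param samples optional subset of sample ids to draw.
#' @param ... unused.
#' @return A ggplot object with the ppm axis reversed, one line per sample.
#' @method autoplot nmr_spectra
#' @export
autoplot.nmr_spectra <- function(object, samples = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(samples)) df <- dplyr::filter(df, .data$sample_id %in% samples)
  ggplot2::ggplot(df, ggplot2::aes(.data$ppm, .data$intensity,
                                   group = .data$sample_id,
                                   colour = .data$sample_id)) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = nrow(object)[1] <= 12) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Chemical shift (ppm)", y = "Intensity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
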