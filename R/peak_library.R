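#' Built-in library of urinary metabolite peak patterns
#'
#' Returns the package's default panel of urinary metabolites as a tibble of
#' multiplets, one row per multiplet. The panel covers the markers most often
#' discussed in urinary NMR studies of hepatotoxic exposure — microbial
#' co-metabolites (hippurate, p-cresol sulphate and glucuronide,
#' phenylacetylglycine, trimethylamine, 3-HPPA), liver-associated species
#' (tyrosine, bile acids), one-carbon intermediates (N-methylnicotinamide,
#' formate, creatine, taurine) and background urinary metabolites (creatinine,
#' citrate, pyruvate). Chemical-shift positions and multiplicities are nominal
#' values from public spectral databases; they are configurable defaults, not
#' measurements, and downstream code never depends on their absolute values.
#'
#' @param overrides optional named list: names are metabolite names present in
#'   the library, values are named lists of multiplet fields
#'   (`center_ppm`, `relative_intensity`, `n_lines`, `j_spacing_ppm`,
#'   `width_ppm`) applied to every multiplet of that metabolite (values are
#'   recycled across the metabolite's multiplets).
#' @return A tibble of class `peak_library` with columns `name`, `center_ppm`,
#'   `relative_intensity`, `n_lines`, `j_spacing_ppm`, `width_ppm`.
#' @examples
#' lib <- make_peak_library()
#' unique(lib$name)
#' # silence hippurate entirely:
#' lib0 <- make_peak_library(list(hippurate = list(relative_intensity = 0)))
#' @export
make_peak_library <- function(overrides = NULL) {
  row <- function(name, center, rel, n = 1L, j = 0, w = 0.003) {
    tibble::tibble(name = name, center_ppm = center, relative_intensity = rel,
                   n_lines = as.integer(n), j_spacing_ppm = j, width_ppm = w)
  }
  lib <- dplyr::bind_rows(
    # J spacings in ppm at 600 MHz (8 Hz ~ 0.0133 ppm)
    row("hippurate", c(7.84, 7.64, 7.55, 3.97), c(2, 1, 2, 2),
        c(2L, 3L, 3L, 1L), c(0.013, 0.012, 0.012, 0)),
    row("p-cresol sulphate", c(7.29, 7.21, 2.35), c(2, 2, 3),
        c(2L, 2L, 1L), c(0.014, 0.014, 0)),
    row("p-cresol glucuronide", c(7.05, 6.95, 2.29), c(2, 2, 3),
        c(2L, 2L, 1L), c(0.014, 0.014, 0)),
    row("tyrosine", c(7.19, 6.89, 3.93), c(2, 2, 1),
        c(2L, 2L, 2L), c(0.014, 0.014, 0.009)),
    row("N-methylnicotinamide", c(9.28, 8.97, 8.90, 8.19, 4.48),
        c(1, 1, 1, 1, 3), c(1L, 2L, 2L, 3L, 1L),
        c(0, 0.010, 0.013, 0.011, 0)),
    row("formate", 8.45, 1),
    row("creatine", c(3.93, 3.04), c(2, 3)),
    row("creatinine", c(4.06, 3.05), c(2, 3)),
    row("taurine", c(3.43, 3.27), c(2, 2), c(3L, 3L), c(0.011, 0.011)),
    row("trimethylamine", 2.88, 9),
    row("phenylacetylglycine", c(7.42, 7.36, 3.75, 3.68), c(2, 3, 2, 2),
        c(3L, 3L, 1L, 2L), c(0.012, 0.012, 0, 0.010)),
    row("3-HPPA", c(7.18, 6.80, 2.83, 2.46), c(1, 3, 2, 2),
        c(3L, 2L, 3L, 3L), c(0.013, 0.013, 0.013, 0.013)),
    # steroid C-18 methyl envelope: broad compared to sharp singlets
    row("bile acids", 0.72, 3, 1L, 0, w = 0.012),
    row("citrate", c(2.66, 2.54), c(2, 2), c(2L, 2L), c(0.026, 0.026)),
    row("pyruvate", 2.37, 3)
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("`overrides` must be a fully named list of metabolite names.")
    }
    known_fields <- c("center_ppm", "relative_intensity", "n_lines",
                      "j_spacing_ppm", "width_ppm")
    for (nm in names(overrides)) {
      idx <- which(lib$name == nm)
      if (!length(idx)) {
        abort(sprintf(
          "Unknown metabolite '%s' in `overrides`; library has: %s",
          nm, paste(unique(lib$name), collapse = ", ")))
      }
      ov <- overrides[[nm]]
      bad <- setdiff(names(ov), known_fields)
      if (length(bad)) {
        abort(sprintf("Unknown multiplet field(s) %s for '%s'.",
                      paste(bad, collapse = ", "), nm))
      }
      for (f in names(ov)) {
        lib[[f]][idx] <- rep_len(ov[[f]], length(idx))
      }
    }
  }
  validate_peak_library(lib)
}

validate_peak_library <- function(lib) {
  stopifnot(all(c("name", "center_ppm", "relative_intensity", "n_lines",
                  "j_spacing_ppm", "width_ppm") %in% names(lib)))
  if (any(lib$width_ppm <= 0)) abort("Multiplet widths must be > 0.")
  if (any(lib$relative_intensity < 0)) {
    abort("Relative intensities must be >= 0.")
  }
  if (any(lib$n_lines < 1)) abort("`n_lines` must be >= 1.")
  if (any(lib$j_spacing_ppm < 0)) abort("`j_spacing_ppm` must be >= 0.")
  class(lib) <- c("peak_library", class(tibble::tibble()))
  lib
}

#' Metabolite names in a peak library
#' @param library a [make_peak_library()] tibble.
#' @return Character vector of unique metabolite names.
#' @export
library_metabolites <- function(library) unique(library$name)
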