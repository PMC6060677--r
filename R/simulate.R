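#' Render one synthetic 1D spectrum from a peak library
#'
#' Each multiplet is rendered as `n_lines` Lorentzian lines (binomial
#' intensity pattern, first-order multiplet) centred at
#' `center_ppm + jitter`, spaced by `j_spacing_ppm`, with full width at half
#' maximum `width_ppm`, and scaled by `concentration * relative_intensity`.
#' A smooth low-order polynomial baseline and i.i.d. Gaussian noise are added
#' when their amplitudes are non-zero (both consume the current RNG stream).
#' Lines whose jittered position falls outside the axis are truncated
#' silently: only the on-axis part of the lineshape is rendered.
#'
#' @param library a [make_peak_library()] tibble.
#' @param concentrations named numeric vector or list, metabolite name ->
#'   concentration (>= 0). Metabolites absent from the map contribute nothing.
#' @param axis numeric ppm grid, strictly monotone (either direction).
#' @param jitter named numeric vector, metabolite name -> ppm offset applied
#'   to all of that metabolite's multiplets. Default none.
#' @param noise_sd SD of additive Gaussian noise (intensity units).
#' @param baseline_amplitude scale of the random smooth baseline
#'   (intensity units); 0 disables it.
#' @return Numeric intensity vector of `length(axis)`.
#' @examples
#' lib <- make_peak_library()
#' ax <- seq(9.5, 0.5, length.out = 2000)
#' y <- simulate_spectrum(lib, c(hippurate = 1, formate = 0.5), ax)
#' @export
simulate_spectrum <- function(library, concentrations, axis,
                              jitter = NULL, noise_sd = 0,
                              baseline_amplitude = 0) {
  axis <- as.numeric(axis)
  d <- diff(axis)
  if (!length(axis) || (length(d) && !(all(d > 0) || all(d < 0)))) {
    abort("`axis` must be a strictly monotone ppm grid.")
  }
  conc <- unlist(concentrations)
  if (length(conc) && any(conc < 0)) {
    abort(sprintf("Negative concentration for: %s",
                  paste(names(conc)[conc < 0], collapse = ", ")))
  }
  jit <- unlist(jitter) %||% numeric(0)
  y <- numeric(length(axis))
  use <- library[library$name %in% names(conc), , drop = FALSE]
  for (i in seq_len(nrow(use))) {
    m <- use[i, ]
    ci <- conc[[m$name]]
    if (ci == 0 || m$relative_intensity == 0) next
    centre <- m$center_ppm + (if (m$name %in% names(jit)) jit[[m$name]] else 0)
    n <- m$n_lines
    offs <- (seq_len(n) - (n + 1) / 2) * m$j_spacing_ppm
    wts <- choose(n - 1, seq_len(n) - 1)
    wts <- wts / max(wts)
    gamma <- m$width_ppm / 2      # HWHM; unit peak height at the line centre
    for (k in seq_len(n)) {
      y <- y + ci * m$relative_intensity * wts[k] *
        gamma^2 / ((axis - (centre + offs[k]))^2 + gamma^2)
    }
  }
  if (baseline_amplitude > 0) {
    u <- seq(-1, 1, length.out = length(axis))
    co <- rnorm(4)
    y <- y + baseline_amplitude *
      (co[1] + co[2] * u + co[3] * (2 * u^2 - 1) + co[4] * (4 * u^3 - 3 * u))
  }
  if (noise_sd > 0) y <- y + rnorm(length(axis), sd = noise_sd)
  y
}

#' Describe a synthetic cohort
#'
#' Collects every knob of the cohort simulator. The defaults describe a
#' realistic morning-urine collection measured on a well-shimmed
#' high-field instrument: a wide urinary dilution spread (log-scale SD 0.4),
#' 25% biological coefficient of variation in metabolite excretion, mild
#' residual peak-position jitter for buffered samples (SD 0.0015 ppm,
#' applied per metabolite per sample; pH-sensitive extremes are exercised by
#' raising it), additive noise and residual baseline two orders of magnitude
#' below unit reference peak height, and a residual water hump at 4.8 ppm.
#'
#' @param n_per_class named integer vector, class label -> number of samples.
#'   Labels must come from the closed vocabulary used by [read_sample_table()].
#' @param ppm_range length-2 numeric, low and high ppm bounds of the grid.
#' @param n_points number of grid points (>= 2).
#' @param effect_map named list: class label -> named numeric vector of
#'   fold-change multipliers (> 0) applied to that class's mean concentration
#'   for the named metabolites. Unlisted combinations default to 1.
#' @param dilution_sigma log-scale SD of the per-sample log-normal dilution
#'   factor (>= 0).
#' @param jitter_sd_ppm SD of the per-sample, per-metabolite Gaussian ppm
#'   jitter (>= 0).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param baseline_amplitude amplitude of the smooth random baseline.
#' @param biological_cv coefficient of variation of per-sample metabolite
#'   concentrations around the class mean (log-normal).
#' @param water_residual add a broad residual water hump at 4.8 ppm?
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_class,
                          ppm_range = c(0.5, 9.5),
                          n_points = 6000,
                          effect_map = list(),
                          dilution_sigma = 0.4,
                          jitter_sd_ppm = 0.0015,
                          noise_sd = 0.005,
                          baseline_amplitude = 0.005,
                          biological_cv = 0.25,
                          water_residual = TRUE,
                          seed = 1L) {
  n_per_class <- unlist(n_per_class)
  if (is.null(names(n_per_class)) || any(names(n_per_class) == "")) {
    abort("`n_per_class` must be a named vector of class sizes.")
  }
  if (any(n_per_class < 1)) abort("Every class must have >= 1 sample.")
  if (length(ppm_range) != 2 || ppm_range[1] >= ppm_range[2]) {
    abort("`ppm_range` must be (low, high) with low < high.")
  }
  if (n_points < 2) abort("`n_points` must be >= 2.")
  fc <- unlist(effect_map)
  if (length(fc) && any(fc <= 0)) abort("All fold-changes must be > 0.")
  stopifnot(dilution_sigma >= 0, jitter_sd_ppm >= 0, noise_sd >= 0,
            baseline_amplitude >= 0, biological_cv >= 0)
  structure(list(
    n_per_class = n_per_class, ppm_range = as.numeric(ppm_range),
    n_points = as.integer(n_points), effect_map = effect_map,
    dilution_sigma = dilution_sigma, jitter_sd_ppm = jitter_sd_ppm,
    noise_sd = noise_sd, baseline_amplitude = baseline_amplitude,
    biological_cv = biological_cv, water_residual = isTRUE(water_residual),
    seed = as.integer(seed)
  ), class = "cohort_design")
}

#' Simulate a cohort of urine spectra with known ground truth
#'
#' Draws, per sample and in this fixed order: (1) the log-normal dilution
#' factor; (2) one concentration per library metabolite, log-normal around
#' the class mean (class mean = 1 x fold-change for metabolites named in the
#' design's `effect_map`, mean-one noise with the design's biological CV);
#' (3) one Gaussian ppm jitter per metabolite; (4) the water-hump amplitude
#' (if enabled); (5) baseline coefficients and additive noise inside
#' [simulate_spectrum()]. The whole cohort runs on a single RNG stream seeded
#' from `design$seed`, so identical designs give bit-identical cohorts.
#'
#' @param design a [cohort_design()].
#' @param library a [make_peak_library()] tibble.
#' @return A list of class `nmr_cohort` with elements
#'   \describe{
#'     \item{spectra}{[nmr_spectra] (ppm descending)}
#'     \item{samples}{tibble of per-sample metadata (id, class_label, batch,
#'       gender, age, al_level)}
#'     \item{truth}{ground-truth list: `dilution_factors` (named vector),
#'       `concentrations` (samples x metabolites matrix), `jitter` (same
#'       shape, ppm), `effect_metabolites` (the design's effect map),
#'       `seed`}
#'   }
#' @examples
#' des <- cohort_design(c(case = 4, village_control = 4), n_points = 400,
#'                      ppm_range = c(2, 4), seed = 7)
#' coh <- simulate_cohort(des, make_peak_library())
#' coh$spectra
#' @export
simulate_cohort <- function(design, library = make_peak_library()) {
  stopifnot(inherits(design, "cohort_design"))
  mets <- library_metabolites(library)
  classes <- rep(names(design$n_per_class), design$n_per_class)
  n <- length(classes)
  ids <- sprintf("%s_%02d", classes,
                 unlist(lapply(design$n_per_class, seq_len)))
  axis <- seq(design$ppm_range[2], design$ppm_range[1],
              length.out = design$n_points)
  # mean-one log-normal: CV c ==> sdlog = sqrt(log(1 + c^2))
  sdlog_bio <- sqrt(log(1 + design$biological_cv^2))

  with_seed(design$seed, {
    X <- matrix(0, n, design$n_points)
    dil <- numeric(n)
    conc_mat <- matrix(0, n, length(mets), dimnames = list(ids, mets))
    jit_mat <- matrix(0, n, length(mets), dimnames = list(ids, mets))
    for (i in seq_len(n)) {
      dil[i] <- if (design$dilution_sigma > 0) {
        rlnorm(1, 0, design$dilution_sigma)
      } else 1
      fc <- rep(1, length(mets))
      names(fc) <- mets
      em <- design$effect_map[[classes[i]]]
      if (!is.null(em)) fc[names(em)] <- unlist(em)
      conc <- fc * rlnorm(length(mets), -sdlog_bio^2 / 2, sdlog_bio)
      jit <- if (design$jitter_sd_ppm > 0) {
        rnorm(length(mets), 0, design$jitter_sd_ppm)
      } else rep(0, length(mets))
      names(conc) <- names(jit) <- mets
      conc_mat[i, ] <- conc
      jit_mat[i, ] <- jit
      y <- simulate_spectrum(library, conc, axis, jitter = jit,
                             noise_sd = 0, baseline_amplitude = 0)
      if (design$water_residual) {
        amp <- rlnorm(1, log(4), 0.3)
        y <- y + amp * (0.04^2) / ((axis - 4.8)^2 + 0.04^2)
      }
      y <- dil[i] * y
      if (design$baseline_amplitude > 0 || design$noise_sd > 0) {
        y <- y + simulate_spectrum(library[0, ], numeric(0), axis,
                                   noise_sd = design$noise_sd,
                                   baseline_amplitude =
                                     design$baseline_amplitude)
      }
      X[i, ] <- y
    }
    names(dil) <- ids
    samples <- tibble::tibble(
      id = ids,
      class_label = classes,
      batch = "2009",
      gender = sample(c("male", "female"), n, replace = TRUE),
      age = round(runif(n, 4, 70)),
      al_level = round(rlnorm(n, log(ifelse(classes == "case", 120, 50)),
                              0.8), 1)
    )
    structure(list(
      spectra = nmr_spectra(X, axis, ids),
      samples = samples,
      truth = list(dilution_factors = dil, concentrations = conc_mat,
                   jitter = jit_mat, effect_metabolites = design$effect_map,
                   seed = design$seed)
    ), class = "nmr_cohort")
  })
}

#' @export
print.nmr_cohort <- function(x, ...) {
  cat("<nmr_cohort>\n")
  print(x$spectra)
  print(table(x$samples$class_label))
  invisible(x)
}

#' Nearest grid index of a chemical shift
#' @param ppm ppm axis.
#' @param target ppm value(s).
#' @return Integer index/indices of the nearest grid point(s).
#' @export
ppm_index <- function(ppm, target) {
  vapply(target, function(t) which.min(abs(ppm - t)), integer(1))
}
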