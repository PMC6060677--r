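#' Demo pipeline configuration
#'
#' A self-contained configuration that simulates a cohort with the class
#' structure of a two-collection case-control field study (34 cases, 18
#' household controls, 17 village controls), three designated effect
#' metabolites, and runs the three standard comparisons at reduced
#' permutation counts. `paper_scale = TRUE` switches to the full 1000 model /
#' 10000 loading permutations.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param paper_scale use full-scale permutation counts?
#' @return A pipeline configuration list.
#' @export
demo_config <- function(out_dir = tempfile("metabopls_run_"), seed = 1L,
                        paper_scale = FALSE) {
  list(
    simulate = list(
      n_per_class = list(case = 34, household_control = 18,
                         village_control = 17),
      ppm_range = c(0.5, 9.5), n_points = 1500,
      effect_map = list(
        case = list(hippurate = 0.6, "p-cresol sulphate" = 0.6,
                    "N-methylnicotinamide" = 1.6),
        household_control = list(hippurate = 0.8,
                                 "p-cresol sulphate" = 0.8)
      ),
      seed = seed
    ),
    preprocess = list(exclude = list(c(4.7, 4.9)), pqn_reference = "median",
                      align = TRUE),
    models = list(
      list(name = "model_1", class_a = "case", class_b = "household_control",
           n_orth = 1),
      list(name = "model_2", class_a = "case", class_b = "village_control",
           n_orth = 1),
      list(name = "model_3", class_a = "household_control",
           class_b = "village_control", n_orth = 1)
    ),
    validation = list(
      k_folds = 7,
      n_perm_model = if (paper_scale) 1000 else 199,
      n_perm_loadings = if (paper_scale) 10000 else 499,
      alpha = 0.05, seed = seed
    ),
    stocsy = list(n_drivers = 1),
    out_dir = out_dir
  )
}

read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

validate_pipeline_config <- function(cfg, classes_present) {
  if (is.null(cfg$models) || !length(cfg$models)) {
    abort("Config must define at least one model.")
  }
  for (m in cfg$models) {
    for (f in c("name", "class_a", "class_b")) {
      if (is.null(m[[f]])) abort(sprintf("Model is missing field '%s'.", f))
    }
    missing <- setdiff(c(m$class_a, m$class_b), classes_present)
    if (length(missing)) {
      abort(sprintf("Model '%s' references absent class label(s): %s",
                    m$name, paste(missing, collapse = ", ")))
    }
  }
  if (is.null(cfg$validation$seed)) {
    abort("Config must carry a validation seed (reproducibility is mandatory).")
  }
  invisible(cfg)
}

#' Run the full profiling pipeline
#'
#' Simulates (or loads) a cohort, preprocesses it (region exclusion, PQN,
#' optional RSPA alignment), then for every configured two-class comparison
#' fits an O-PLS-DA model, cross-validates Q2Y, runs the model-level and
#' per-variable permutation tests, traces a STOCSY from the top-|r|
#' variable, runs the demographic univariate battery, and writes a versioned
#' JSON report. Idempotent: identical configs (including seeds) give
#' byte-identical reports.
#'
#' @param config a configuration list (see [demo_config()]) or a path to a
#'   YAML/JSON file with the same structure.
#' @param quiet suppress progress messages?
#' @return Invisibly, a list with the cohort, per-model results and the
#'   report path.
#' @export
run_pipeline <- function(config = demo_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  say <- function(...) if (!quiet) inform(sprintf(...))

  # ingest
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    des <- cohort_design(
      n_per_class = unlist(sim$n_per_class),
      ppm_range = unlist(sim$ppm_range) %||% c(0.5, 9.5),
      n_points = sim$n_points %||% 6000,
      effect_map = sim$effect_map %||% list(),
      dilution_sigma = sim$dilution_sigma %||% 0.4,
      jitter_sd_ppm = sim$jitter_sd_ppm %||% 0.003,
      noise_sd = sim$noise_sd %||% 0.01,
      baseline_amplitude = sim$baseline_amplitude %||% 0.02,
      seed = sim$seed %||% 1L
    )
    validate_pipeline_config(config, names(des$n_per_class))
    say("simulate: %d samples x %d points (seed %d)",
        sum(des$n_per_class), des$n_points, des$seed)
    cohort <- simulate_cohort(des)
    spectra <- cohort$spectra
    samples <- validate_sample_table(cohort$samples)
  } else {
    if (is.null(config$input$spectra) || is.null(config$input$samples)) {
      abort("Config needs either a `simulate` block or `input` paths.")
    }
    spectra <- read_spectra(config$input$spectra)
    samples <- read_sample_table(config$input$samples)
    validate_pipeline_config(config, unique(samples$class_label))
    cohort <- NULL
    say("load: %d samples x %d points", nrow(spectra)[1], length(spectra$ppm))
  }

  # preprocess
  pp <- config$preprocess %||% list()
  regions <- region_set(c(pp$exclude %||% list(c(4.7, 4.9)),
                          pp$remove %||% list()))
  spectra <- exclude_regions(spectra, regions)
  say("exclude: %d region(s), %d points remain", nrow(regions),
      length(spectra$ppm))
  pq <- pqn_normalize(spectra, reference = pp$pqn_reference %||% "median")
  spectra <- pq$spectra
  say("pqn: quotients in [%.3f, %.3f]", min(pq$quotients), max(pq$quotients))
  shifts <- NULL
  if (isTRUE(pp$align %||% TRUE)) {
    al <- rspa_align(spectra, params = do.call(
      alignment_params, pp$alignment %||% list()))
    spectra <- al$spectra
    shifts <- al$shifts
    say("rspa: max |shift| %d point(s)", max(abs(al$shifts$shift)))
  }

  val <- config$validation
  model_results <- purrr::map(config$models, function(mc) {
    say("model %s: %s vs %s (n_orth=%d)", mc$name, mc$class_a, mc$class_b,
        mc$n_orth %||% 0)
    keep <- samples$class_label %in% c(mc$class_a, mc$class_b)
    X <- spectra$intensities[samples$id[keep], , drop = FALSE]
    y <- class_vector(samples$class_label[keep], positive = mc$class_a)
    group <- if ("subject" %in% names(samples)) samples$subject[keep] else NULL
    n_orth <- mc$n_orth %||% 0L

    sc <- scale_uv(nmr_spectra(X, spectra$ppm, samples$id[keep]))
    fit <- fit_opls_da(sc$X, y, n_orth = n_orth, scaling_state = sc$state)
    cv <- cross_validate_q2(X, y, n_orth, k_folds = val$k_folds %||% 7,
                            seed = val$seed, group = group)
    pm <- permutation_test_model(X, y, n_orth,
                                 n_perm = val$n_perm_model %||% 199,
                                 k_folds = val$k_folds %||% 7,
                                 seed = val$seed, group = group)
    lo <- permutation_test_loadings(X, y, n_orth,
                                    n_perm = val$n_perm_loadings %||% 499,
                                    alpha = val$alpha %||% 0.05,
                                    seed = val$seed)
    say("  Q2Y=%.3f perm_p=%.4g, %d significant variable(s)",
        cv$q2y, pm$p_value, sum(lo$significant))
    top <- lo$variable[order(-abs(lo$r_obs))][seq_len(
      min(config$stocsy$n_drivers %||% 1, nrow(lo)))]
    st <- purrr::map(top, function(v) stocsy(spectra, driver_index = v))
    list(config = mc, fit = fit, cv = cv, perm = pm, loadings = lo,
         stocsy = st, n_per_class = table(samples$class_label[keep]), y = y)
  })

  # univariate battery on the metadata (where available)
  univariate <- list()
  cls <- samples$class_label
  if (all(c("case", "village_control") %in% cls) &&
      "al_level" %in% names(samples)) {
    al_case <- samples$al_level[cls == "case"]
    al_vc <- samples$al_level[cls == "village_control"]
    if (sum(!is.na(al_case)) >= 2 && sum(!is.na(al_vc)) >= 2 &&
        all(c(al_case, al_vc) > 0, na.rm = TRUE)) {
      univariate$al_t_test <- t_test(al_vc, al_case, log_transform = TRUE,
                                     tail = "one")
      univariate$al_geometric_means <- dplyr::bind_rows(
        case = geometric_mean_ci(al_case[!is.na(al_case)]),
        village_control = geometric_mean_ci(al_vc[!is.na(al_vc)]),
        .id = "class")
    }
  }
  if ("gender" %in% names(samples) && length(unique(cls)) >= 2 &&
      length(unique(samples$gender)) == 2) {
    univariate$gender_chi_square <-
      chi_square(table(samples$gender, cls %in% "case"))
  }
  if ("age" %in% names(samples) &&
      all(c("case", "village_control") %in% cls)) {
    univariate$age_t_test <- t_test(samples$age[cls == "case"],
                                    samples$age[cls == "village_control"])
  }

  # report
  out_dir <- config$out_dir %||% tempfile("metabopls_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summaries <- purrr::map(model_results, function(r) {
    list(name = r$config$name,
         comparison = sprintf("%s vs %s", r$config$class_a, r$config$class_b),
         n_per_class = as.list(r$n_per_class),
         n_orth = r$fit$n_orth, R2X = r$fit$r2x, R2Y = r$fit$r2y)
  })
  validations <- purrr::map(model_results, function(r) {
    sig <- dplyr::filter(
      tibble::as_tibble(r$loadings)[, c("variable", "ppm", "r_obs", "p_value")],
      r$loadings$significant)
    list(Q2Y = r$cv$q2y, perm_p = r$perm$p_value,
         significant_variables = sig)
  })
  report_path <- file.path(out_dir, "report.json")
  write_report(summaries, validations, report_path)
  if (!is.null(cohort)) {
    write_ground_truth(cohort$truth, file.path(out_dir, "ground_truth.json"))
  }
  say("report: %s", report_path)
  invisible(list(cohort = cohort, spectra = spectra, samples = samples,
                 shifts = shifts, models = model_results,
                 univariate = univariate, report_path = report_path))
}
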