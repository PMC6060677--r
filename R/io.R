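#' Closed vocabulary of sample class labels
#' @export
CLASS_LEVELS <- c("case", "household_control", "village_control",
                  "pre_dose", "post_dose", "al_only", "al_ddt")

#' Write a spectra matrix to CSV
#'
#' Layout: first row is the ppm axis (header cell `sample_id`), then one row
#' per sample, first column the sample id. Byte output is deterministic for a
#' fixed input (numbers are written with full `%.10g` precision).
#'
#' @param spectra an [nmr_spectra] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "nmr_spectra"))
  if (nrow(spectra$intensities) == 0) abort("Refusing to write an empty spectra matrix.")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("sample_id", sprintf("%.10g", spectra$ppm)),
                   collapse = ","), con)
  for (i in seq_len(nrow(spectra$intensities))) {
    writeLines(paste(c(rownames(spectra$intensities)[i],
                       sprintf("%.10g", spectra$intensities[i, ])),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read a spectra matrix from CSV
#'
#' Expects the layout written by [write_spectra()]. The ppm axis is taken
#' from the header row; an ascending axis is reversed (with a warning) to the
#' descending convention.
#'
#' @param path CSV file path.
#' @return An [nmr_spectra] object.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2) abort("Spectra file needs a ppm header and >= 1 sample row.")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  ppm <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(ppm)) {
    abort(sprintf("Non-numeric ppm value in header column(s): %s",
                  paste(which(is.na(ppm)) + 1, collapse = ", ")))
  }
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(header))) {
    abort(sprintf("Ragged row(s) %s: expected %d fields.",
                  paste(which(widths != length(header)) + 1, collapse = ", "),
                  length(header)))
  }
  ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate sample id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(length(ppm))))
  X <- t(matrix(vals, nrow = length(ppm)))
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-numeric intensity at row %d (sample '%s'), column %d.",
                  bad[1] + 1, ids[bad[1]], bad[2] + 1))
  }
  nmr_spectra(X, ppm, ids)
}

#' Read and validate a sample metadata table
#'
#' Requires columns `id` and `class_label`; recognises the optional typed
#' columns `batch`, `gender`, `age`, `al_level`, `alt`,
#' `histopathology_score`, `duration_months` and `subject`. Class labels are
#' normalised case-insensitively (spaces and hyphens become underscores) and
#' must come from the closed vocabulary in [CLASS_LEVELS]. Empty cells stay
#' missing (`NA`); nothing is imputed.
#'
#' @param path CSV file path.
#' @return A validated tibble of class `sample_table`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validate_sample_table(tibble::as_tibble(df))
}

#' Validate an in-memory sample table
#' @param df data frame of per-sample metadata.
#' @return The validated, normalised tibble (class `sample_table`).
#' @export
validate_sample_table <- function(df) {
  df <- tibble::as_tibble(df)
  req <- c("id", "class_label")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    abort(sprintf("Missing required column(s): %s", paste(miss, collapse = ", ")))
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    abort(sprintf("Duplicate sample id(s): %s",
                  paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  }
  norm <- gsub("[ -]+", "_", tolower(trimws(as.character(df$class_label))))
  bad <- setdiff(unique(norm), CLASS_LEVELS)
  if (length(bad)) {
    abort(sprintf("Unknown class label(s) %s; allowed: %s",
                  paste(bad, collapse = ", "),
                  paste(CLASS_LEVELS, collapse = ", ")))
  }
  df$class_label <- norm
  for (col in c("age", "al_level", "alt", "duration_months")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  if ("al_level" %in% names(df) &&
      any(df$al_level < 0, na.rm = TRUE)) {
    abort("`al_level` must be >= 0 where present.")
  }
  if ("histopathology_score" %in% names(df)) {
    hs <- as.integer(df$histopathology_score)
    if (any(!is.na(hs) & (hs < 1 | hs > 5))) {
      abort("`histopathology_score` must lie in 1..5.")
    }
    df$histopathology_score <- hs
  }
  class(df) <- c("sample_table", class(tibble::tibble()))
  df
}

#' Write a machine-readable model report
#'
#' Serialises one block per fitted model — class comparison, per-class sample
#' sizes, number of orthogonal components, R2X, R2Y, cross-validated Q2Y, the
#' model-level permutation p-value and the per-variable significant loadings
#' (always a list, possibly empty) — to versioned JSON.
#'
#' @param model_summaries list of per-model lists; each needs at least
#'   `name`, `comparison`, `n_per_class`, `n_orth`, `R2X`, `R2Y`.
#' @param validation_results list (same length/order) of lists with `Q2Y`,
#'   `perm_p`, and optionally `significant_variables` (data frame or list).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(model_summaries, validation_results, path) {
  if (length(model_summaries) != length(validation_results)) {
    abort("One validation result is required per model summary.")
  }
  blocks <- purrr::map2(model_summaries, validation_results, function(m, v) {
    sig <- v$significant_variables
    if (is.null(sig)) sig <- list()
    if (is.data.frame(sig)) sig <- purrr::transpose(as.list(sig)) %||% list()
    list(name = m$name, comparison = m$comparison,
         n_per_class = as.list(m$n_per_class),
         n_orth = m$n_orth, R2X = m$R2X, R2Y = m$R2Y,
         Q2Y = v$Q2Y, perm_p = v$perm_p,
         significant_variables = sig)
  })
  report <- list(schema = "metabopls-report/1", models = blocks)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "list")
  invisible(path)
}

#' Read a model report written by [write_report()]
#' @param path JSON path.
#' @return The parsed report list.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(rep$schema, "metabopls-report/1")) {
    abort("Unrecognised report schema.")
  }
  rep
}

#' Write cohort ground truth as JSON
#' @param truth the `truth` element of an [simulate_cohort()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    schema = "metabopls-truth/1",
    seed = truth$seed,
    dilution_factors = as.list(truth$dilution_factors),
    effect_metabolites = truth$effect_metabolites,
    jitter = apply(truth$jitter, 1, as.list, simplify = FALSE),
    concentrations = apply(truth$concentrations, 1, as.list, simplify = FALSE)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
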