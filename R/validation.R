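# Stratified k-fold assignment; samples sharing a non-NA `group` id are kept
# in the same fold. Guarantees (by retrying) that every training split
# contains both classes.
make_folds <- function(y, k, group = NULL, max_retry = 25L) {
  n <- length(y)
  units <- if (is.null(group)) as.character(seq_len(n)) else as.character(group)
  for (r in seq_len(max_retry)) {
    fold <- integer(n)
    for (cl in unique(y)) {
      u_cl <- unique(units[y == cl])
      u_cl <- sample(u_cl)
      f <- rep(seq_len(k), length.out = length(u_cl))
      for (j in seq_along(u_cl)) {
        fold[units == u_cl[j] & y == cl] <- f[j]
      }
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y[fold != f])) == 2 && any(fold == f)
    }, logical(1)))
    if (ok) return(fold)
  }
  abort("Could not build folds with both classes in every training split.")
}

# CV engine shared by cross_validate_q2 and the permutation tests.
# X is the preprocessed but UNscaled matrix; scaling is refit per fold.
cv_press <- function(X, y, n_orth, k_folds, fold) {
  yhat <- numeric(length(y))
  for (f in unique(fold)) {
    tr <- fold != f
    sc <- scale_uv(X[tr, , drop = FALSE])
    m <- fit_opls_da(sc$X, y[tr], n_orth = n_orth)
    Xte <- apply_scaling(X[!tr, , drop = FALSE], sc$state)
    yhat[!tr] <- predict(m, Xte)$y_hat
  }
  yhat
}

#' Cross-validated Q2 of an O-PLS-DA model
#'
#' Stratified k-fold cross-validation with no leakage: unit-variance scaling
#' is refit on every training split and applied to the held-out samples, the
#' model is refit, and the held-out class values are predicted. Q2Y = 1 -
#' PRESS/TSS with TSS about the grand mean of y.
#'
#' @param X preprocessed, unscaled matrix (samples x variables) or an
#'   [nmr_spectra] object.
#' @param y 0/1 class dummy or two-level label vector.
#' @param n_orth orthogonal components of the refitted models.
#' @param k_folds number of folds (default 7).
#' @param seed integer seed controlling the fold draw.
#' @param group optional per-sample subject ids; samples sharing an id stay
#'   in the same fold (longitudinal sampling).
#' @return A list of class `cv_result`: `q2y`, `press`, `tss`,
#'   `fold_assignments`, `y_hat_cv`, `seed`.
#' @export
cross_validate_q2 <- function(X, y, n_orth = 0L, k_folds = 7L, seed = 1L,
                              group = NULL) {
  if (!is.numeric(y) || !all(y %in% c(0, 1))) y <- class_vector(y)
  if (inherits(X, "nmr_spectra")) X <- X$intensities
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k_folds) abort("Fewer samples than folds.")
  if (min(table(y)) < 2) abort("Each class needs >= 2 samples.")
  fold <- with_seed(seed, make_folds(y, k_folds, group))
  yhat <- cv_press(X, y, n_orth, k_folds, fold)
  press <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(q2y = 1 - press / tss, press = press, tss = tss,
                 fold_assignments = fold, y_hat_cv = yhat,
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(Q2Y = x$q2y, PRESS = x$press, TSS = x$tss, seed = x$seed)
}

#' Permutation test of model validity
#'
#' The observed statistic is the cross-validated Q2Y on the true class
#' labels. For each permutation the labels are shuffled and the full
#' procedure — fold construction, per-fold scaling, O-PLS fit,
#' cross-validated prediction — is recomputed. The one-sided p-value uses
#' the add-one correction p = (1 + #\{null >= observed\}) / (1 + n_perm), so
#' p is never zero and its floor at n_perm = 1000 is 1/1001.
#'
#' @inheritParams cross_validate_q2
#' @param n_perm number of label permutations (>= 1).
#' @return A list of class `perm_result`: `observed` Q2Y, `null_values`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
permutation_test_model <- function(X, y, n_orth = 0L, n_perm = 1000L,
                                   k_folds = 7L, seed = 1L, group = NULL) {
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  if (!is.numeric(y) || !all(y %in% c(0, 1))) y <- class_vector(y)
  if (inherits(X, "nmr_spectra")) X <- X$intensities
  X <- as.matrix(X)
  obs <- cross_validate_q2(X, y, n_orth, k_folds, seed = seed,
                           group = group)$q2y
  null_values <- with_seed(child_seed(seed, 0L), {
    vapply(seq_len(n_perm), function(i) {
      yp <- sample(y)
      fold <- make_folds(yp, k_folds, group)
      yhat <- cv_press(X, yp, n_orth, k_folds, fold)
      1 - sum((yp - yhat)^2) / sum((yp - mean(yp))^2)
    }, numeric(1))
  })
  structure(list(observed = obs, null_values = null_values,
                 p_value = (1 + sum(null_values >= obs)) / (1 + n_perm),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "perm_result")
}

#' @method glance perm_result
#' @export
glance.perm_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, p_value = x$p_value,
                 n_perm = x$n_perm, seed = x$seed)
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> observed Q2Y = %.3f, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Permutation significance of per-variable loadings
#'
#' The observed statistic per variable is |r|, the absolute Pearson
#' correlation of that (scaled) column with the predictive score of the
#' model fitted on the true labels. The null refits the model under label
#' permutation and records every variable's |r|, giving a per-variable
#' add-one-corrected p-value. Variables with p < alpha are flagged. An
#' optional Benjamini-Hochberg adjustment is available but off by default
#' (per-variable alpha is the conventional reporting rule).
#'
#' @inheritParams cross_validate_q2
#' @param n_perm number of label permutations.
#' @param alpha significance level for flagging.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble of class `loading_significance`: `variable`, `ppm`
#'   (when the scaled input carries an axis), `r_obs`, `p_value`,
#'   `significant`; attributes `n_perm`, `alpha`, `seed`.
#' @export
permutation_test_loadings <- function(X, y, n_orth = 0L, n_perm = 10000L,
                                      alpha = 0.05, seed = 1L,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  if (!is.numeric(y) || !all(y %in% c(0, 1))) y <- class_vector(y)
  sc <- scale_uv(X)
  model <- fit_opls_da(sc$X, y, n_orth = n_orth, scaling_state = sc$state)
  obs <- abs(model$loading_r)
  exceed <- integer(length(obs))
  with_seed(child_seed(seed, 1L), {
    for (i in seq_len(n_perm)) {
      yp <- sample(y)
      mp <- fit_opls_da(sc$X, yp, n_orth = n_orth)
      exceed <- exceed + (abs(mp$loading_r) >= obs)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  p_use <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  out <- tibble::tibble(
    variable = sc$state$kept_columns,
    ppm = if (!is.null(sc$state$ppm)) sc$state$ppm else NA_real_,
    r_obs = model$loading_r,
    p_value = p,
    significant = p_use < alpha
  )
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("loading_significance", class(tibble::tibble()))
  out
}
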