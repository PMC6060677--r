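#' Encode a two-class factor as a 0/1 dummy
#' @param labels vector of class labels (exactly two distinct values).
#' @param positive optional label coded 1; default: the second sorted level.
#' @return Numeric 0/1 vector with a `class_names` attribute.
#' @export
class_vector <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) {
    abort(sprintf("Need exactly two classes, got: %s",
                  paste(lev, collapse = ", ")))
  }
  pos <- positive %||% lev[2]
  if (!pos %in% lev) abort(sprintf("No class '%s' present.", pos))
  y <- as.numeric(labels == pos)
  attr(y, "class_names") <- c(`0` = setdiff(lev, pos), `1` = pos)
  y
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) abort("`X` rows and `y` length differ.")
  if (length(unique(y)) < 2) abort("`y` contains a single class/value.")
  list(X = X, y = y)
}

# one NIPALS PLS1 component on (already deflated) X, centred y.
# Closed form for a single y column: w = X'y / ||X'y||.
pls1_component <- function(X, yc) {
  w <- as.numeric(crossprod(X, yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) abort("X'y is zero: no class-correlated variance left.")
  w <- w / nw
  t <- as.numeric(X %*% w)
  tt <- sum(t^2)
  c_ <- sum(yc * t) / tt
  p <- as.numeric(crossprod(X, t)) / tt
  list(w = w, t = t, c = c_, p = p)
}

#' Fit a PLS-DA model (NIPALS PLS1)
#'
#' Sequential NIPALS components against a single 0/1 class dummy: per
#' component w = X'y (unit norm), t = Xw, c = y't/t't, p = X't/t't, then X
#' and y are deflated. `X` must already be column-centred (typically
#' UV-scaled with [scale_uv()]); `y` is centred internally.
#'
#' @param X centred/scaled matrix (samples x variables).
#' @param y 0/1 class dummy (see [class_vector()]).
#' @param n_components number of components (>= 1, <= rank bound).
#' @param scaling_state optional [scale_uv()] state carried along for
#'   back-scaled loadings.
#' @return A list of class `pls_model`: matrices `W`, `P`, `T`, vector `C`,
#'   cumulative `r2x`/`r2y` per component, `y_mean`, `loading_r`
#'   (correlation of each X column with the first score), `scaling_state`.
#' @export
fit_pls_da <- function(X, y, n_components = 1L, scaling_state = NULL) {
  xy <- check_xy(X, y)
  X0 <- xy$X
  n_components <- as.integer(n_components)
  rank_bound <- min(nrow(X0) - 1L, ncol(X0))
  if (n_components < 1L) abort("`n_components` must be >= 1.")
  if (n_components > rank_bound) {
    abort(sprintf("`n_components` (%d) exceeds the rank bound (%d).",
                  n_components, rank_bound))
  }
  y_mean <- mean(xy$y)
  yc <- xy$y - y_mean
  ssy <- sum(yc^2)
  ssx <- sum(X0^2)
  Xd <- X0
  W <- P <- matrix(0, ncol(X0), n_components)
  Tm <- matrix(0, nrow(X0), n_components)
  C <- numeric(n_components)
  r2x <- r2y <- numeric(n_components)
  ycd <- yc
  for (a in seq_len(n_components)) {
    cmp <- pls1_component(Xd, ycd)
    # sign convention: scores positively correlated with the class dummy
    if (sum(cmp$t * yc) < 0) {
      cmp$w <- -cmp$w; cmp$t <- -cmp$t; cmp$c <- -cmp$c; cmp$p <- -cmp$p
    }
    W[, a] <- cmp$w; P[, a] <- cmp$p; Tm[, a] <- cmp$t; C[a] <- cmp$c
    Xd <- Xd - tcrossprod(cmp$t, cmp$p)
    ycd <- ycd - cmp$t * cmp$c
    r2x[a] <- 1 - sum(Xd^2) / ssx
    r2y[a] <- 1 - sum(ycd^2) / ssy
  }
  structure(list(
    W = W, P = P, T = Tm, C = C, n_components = n_components,
    r2x = r2x, r2y = r2y, y_mean = y_mean,
    loading_r = as.numeric(cor(Tm[, 1], X0)),
    scaling_state = scaling_state,
    class_names = attr(y, "class_names")
  ), class = "pls_model")
}

#' Fit an O-PLS-DA model
#'
#' Orthogonal signal correction followed by one predictive PLS1 component.
#' For each of `n_orth` rounds, the current PLS weight/loading pair (w, p)
#' yields an orthogonal weight w_orth = p - (w'p) w (normalised); the
#' orthogonal score t_orth = X w_orth and loading
#' p_orth = X' t_orth / (t_orth' t_orth) are removed from X before the next
#' round. The final predictive component is fitted on the filtered matrix.
#' With `n_orth = 0` the model is exactly a one-component PLS-DA.
#'
#' @inheritParams fit_pls_da
#' @param n_orth number of orthogonal components (>= 0).
#' @return A list of class `opls_model` (inherits `pls_model`): unit-norm
#'   predictive weight `w`, loading `p`, scores `t` (the cross-validatable
#'   predictive axis), y-loading `c`, orthogonal `W_orth`/`P_orth`/`T_orth`,
#'   `n_orth`, `r2x` (all components, including orthogonal), `r2y`,
#'   `loading_r` (per-variable Pearson correlation of the original scaled
#'   columns with `t`), `y_mean`, `scaling_state`.
#' @examples
#' X <- scale(matrix(rnorm(60), 10, 6), scale = FALSE)
#' y <- rep(c(0, 1), each = 5)
#' m <- fit_opls_da(X, y, n_orth = 1)
#' glance(m)
#' @export
fit_opls_da <- function(X, y, n_orth = 0L, scaling_state = NULL) {
  xy <- check_xy(X, y)
  X0 <- xy$X
  n_orth <- as.integer(n_orth)
  if (n_orth < 0L) abort("`n_orth` must be >= 0.")
  if (n_orth + 1L > min(nrow(X0) - 1L, ncol(X0))) {
    abort("Too many orthogonal components for the data's rank.")
  }
  y_mean <- mean(xy$y)
  yc <- xy$y - y_mean
  ssx <- sum(X0^2)
  ssy <- sum(yc^2)
  Xd <- X0
  W_orth <- P_orth <- matrix(0, ncol(X0), n_orth)
  T_orth <- matrix(0, nrow(X0), n_orth)
  r2x_orth <- 0
  for (k in seq_len(n_orth)) {
    cmp <- pls1_component(Xd, yc)
    w_o <- cmp$p - sum(cmp$w * cmp$p) * cmp$w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) {
      abort(sprintf("No orthogonal variance left at component %d.", k))
    }
    w_o <- w_o / nw
    t_o <- as.numeric(Xd %*% w_o)
    p_o <- as.numeric(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_orth[, k] <- w_o; P_orth[, k] <- p_o; T_orth[, k] <- t_o
    r2x_orth <- r2x_orth + sum(t_o^2) * sum(p_o^2) / ssx
  }
  cmp <- pls1_component(Xd, yc)
  if (sum(cmp$t * yc) < 0) {
    cmp$w <- -cmp$w; cmp$t <- -cmp$t; cmp$c <- -cmp$c; cmp$p <- -cmp$p
  }
  resid_y <- yc - cmp$t * cmp$c
  structure(list(
    w = cmp$w, p = cmp$p, t = cmp$t, c = cmp$c,
    W_orth = W_orth, P_orth = P_orth, T_orth = T_orth, n_orth = n_orth,
    r2x = sum(cmp$t^2) * sum(cmp$p^2) / ssx + r2x_orth,
    r2y = 1 - sum(resid_y^2) / ssy,
    loading_r = as.numeric(cor(cmp$t, X0)),
    y_mean = y_mean, scaling_state = scaling_state,
    class_names = attr(y, "class_names")
  ), class = c("opls_model", "pls_model"))
}

#' Predict scores and class values for new samples
#'
#' New rows must be scaled with the training scaling state
#' (see [apply_scaling()]). The training orthogonal filter is applied
#' sequentially, then the predictive score and fitted class value are
#' computed.
#'
#' @param object a fitted [fit_opls_da()] model.
#' @param newdata matrix with the model's variables as columns.
#' @param ... unused.
#' @return A list: `t` (predictive scores), `t_orth` (matrix of orthogonal
#'   scores), `y_hat` (fitted class values on the 0/1 scale).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != length(object$w)) {
    abort(sprintf("`newdata` has %d columns; the model was trained on %d.",
                  ncol(Xn), length(object$w)))
  }
  t_orth <- matrix(0, nrow(Xn), object$n_orth)
  for (k in seq_len(object$n_orth)) {
    t_o <- as.numeric(Xn %*% object$W_orth[, k])
    Xn <- Xn - tcrossprod(t_o, object$P_orth[, k])
    t_orth[, k] <- t_o
  }
  t_new <- as.numeric(Xn %*% object$w)
  list(t = t_new, t_orth = t_orth,
       y_hat = t_new * object$c + object$y_mean)
}

#' Back-scaled covariance loadings
#'
#' Multiplies the predictive loading of each variable by that variable's
#' training SD, recovering a spectrum-like covariance profile, and pairs it
#' with the loading correlation r (colouring variable of the classical
#' O-PLS-DA loadings plot).
#'
#' @param model a fitted [fit_opls_da()] model.
#' @param scaling_state optional [scale_uv()] state; defaults to the one
#'   stored in the model.
#' @return A tibble of class `loadings_profile`: `variable` (column index in
#'   the pre-scaling matrix), `ppm` (when known), `backscaled`, `r`, `abs_r`.
#'   Variables dropped at scaling (zero variance) are absent.
#' @export
backscaled_loadings <- function(model, scaling_state = NULL) {
  state <- scaling_state %||% model$scaling_state
  if (is.null(state)) abort("No scaling state available for back-scaling.")
  k <- state$kept_columns
  if (length(k) != length(model$p)) {
    abort("Scaling state does not match the model's variables.")
  }
  out <- tibble::tibble(
    variable = k,
    ppm = if (!is.null(state$ppm)) state$ppm else NA_real_,
    backscaled = model$p * state$column_sds[k],
    r = model$loading_r,
    abs_r = abs(model$loading_r)
  )
  class(out) <- c("loadings_profile", class(tibble::tibble()))
  out
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "<opls_model> 1 predictive + %d orthogonal component(s); R2X=%.3f R2Y=%.3f\n",
    x$n_orth, x$r2x, x$r2y))
  invisible(x)
}

#' @export
print.pls_model <- function(x, ...) {
  if (inherits(x, "opls_model")) return(NextMethod())
  cat(sprintf("<pls_model> %d component(s); R2X=%.3f R2Y=%.3f\n",
              x$n_components, tail(x$r2x, 1), tail(x$r2y, 1)))
  invisible(x)
}
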