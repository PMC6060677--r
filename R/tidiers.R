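#' Tidy an O-PLS-DA model
#'
#' @param x a fitted [fit_opls_da()] model.
#' @param ... unused.
#' @return A tibble with one row per modelled variable: `variable`, `ppm`
#'   (when a scaling state with an axis is attached), predictive `weight`
#'   and `loading`, and the loading correlation `r`.
#' @method tidy opls_model
#' @export
tidy.opls_model <- function(x, ...) {
  st <- x$scaling_state
  tibble::tibble(
    variable = if (!is.null(st)) st$kept_columns else seq_along(x$w),
    ppm = if (!is.null(st) && !is.null(st$ppm)) st$ppm else NA_real_,
    weight = x$w,
    loading = x$p,
    r = x$loading_r
  )
}

#' @rdname tidy.opls_model
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  if (inherits(x, "opls_model")) return(tidy.opls_model(x, ...))
  st <- x$scaling_state
  purrr::map_dfr(seq_len(x$n_components), function(a) {
    tibble::tibble(
      component = a,
      variable = if (!is.null(st)) st$kept_columns else seq_len(nrow(x$W)),
      weight = x$W[, a],
      loading = x$P[, a]
    )
  })
}

#' One-row summary of a fitted model
#' @param x a `pls_model` or `opls_model`.
#' @param ... unused.
#' @return A tibble with `n`, component counts, `R2X`, `R2Y`.
#' @method glance opls_model
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(n = length(x$t), n_orth = x$n_orth,
                 R2X = x$r2x, R2Y = x$r2y)
}

#' @rdname glance.opls_model
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  if (inherits(x, "opls_model")) return(glance.opls_model(x, ...))
  tibble::tibble(n = nrow(x$T), n_components = x$n_components,
                 R2X = tail(x$r2x, 1), R2Y = tail(x$r2y, 1))
}

#' Score plot of an O-PLS-DA model
#'
#' Cross-validated-style predictive scores (x) against the first orthogonal
#' scores (y), the standard two-axis view of a case-control O-PLS-DA model.
#'
#' @param object a fitted [fit_opls_da()] model with `n_orth >= 1` (with 0
#'   orthogonal components the y axis is the sample index).
#' @param labels optional per-sample class labels for colouring.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot opls_model
#' @export
autoplot.opls_model <- function(object, labels = NULL, ...) {
  df <- tibble::tibble(
    t = object$t,
    t_orth = if (object$n_orth >= 1) object$T_orth[, 1] else
      seq_along(object$t),
    label = if (!is.null(labels)) as.character(labels) else "sample"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$t_orth,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Predictive score (Tcv)",
                  y = if (object$n_orth >= 1) "Orthogonal score (TYosc)"
                      else "Sample index",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Back-scaled loadings plot coloured by |r|
#' @param object a [backscaled_loadings()] tibble.
#' @param ... unused.
#' @return A ggplot object (ppm axis reversed when available).
#' @method autoplot loadings_profile
#' @export
autoplot.loadings_profile <- function(object, ...) {
  has_ppm <- !all(is.na(object$ppm))
  x <- if (has_ppm) "ppm" else "variable"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data[[x]], .data$backscaled,
                                    colour = .data$abs_r)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1), name = "|r|") +
    ggplot2::labs(x = if (has_ppm) "Chemical shift (ppm)" else "Variable",
                  y = "Back-scaled loading (covariance)") +
    ggplot2::theme_minimal()
  if (has_ppm) p <- p + ggplot2::scale_x_reverse()
  p
}
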