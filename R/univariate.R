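test_result <- function(method, statistic, p_value, tail, n) {
  out <- tibble::tibble(method = method, statistic = statistic,
                        p_value = min(max(p_value, .Machine$double.xmin), 1),
                        tail = tail)
  for (nm in names(n)) out[[nm]] <- n[[nm]]
  class(out) <- c("test_result", class(tibble::tibble()))
  out
}

# exact null distribution of U = #{pairs (a_i, b_j): a_i > b_j} + ties/2,
# by enumeration of all C(N, n_a) group assignments of the pooled values.
mw_exact_null <- function(pooled, n_a) {
  combos <- utils::combn(length(pooled), n_a)
  apply(combos, 2, function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
}

mw_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups with midrank tie handling.
#' For pooled sizes of at most `exact_max` the p-value is computed by exact
#' enumeration of all group assignments (valid under ties); otherwise by the
#' normal approximation with tie-corrected variance and continuity
#' correction. The one-tailed version tests whether the first group tends to
#' take smaller values (lower tail of U).
#'
#' @param a,b numeric vectors (each non-empty).
#' @param tail `"two"` or `"one"`.
#' @param exact_max largest pooled size for exact enumeration.
#' @return A one-row `test_result` tibble: `method`, `statistic` (U for the
#'   first group), `p_value`, `tail`, `n_a`, `n_b`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4), tail = "one")
#' @export
mann_whitney <- function(a, b, tail = c("two", "one"), exact_max = 10L) {
  tail <- match.arg(tail)
  a <- as.numeric(a[!is.na(a)])
  b <- as.numeric(b[!is.na(b)])
  if (!length(a) || !length(b)) abort("Both groups must be non-empty.")
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  u <- mw_u(a, b)
  mu <- n_a * n_b / 2
  if (N <= exact_max) {
    null_u <- mw_exact_null(c(a, b), n_a)
    p <- if (tail == "one") {
      mean(null_u <= u)
    } else {
      mean(abs(null_u - mu) >= abs(u - mu))
    }
  } else {
    ranks <- rank(c(a, b))
    ties <- table(ranks)
    sigma2 <- n_a * n_b / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else if (tail == "one") {
      p <- pnorm((u - mu + 0.5) / sqrt(sigma2))
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * pnorm(-max(z, 0))
    }
  }
  test_result("Mann-Whitney U", u, p, tail, list(n_a = n_a, n_b = n_b))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of midranks; the p-value uses the
#' t-approximation with n - 2 degrees of freedom. Incomplete pairs are
#' dropped.
#'
#' @param x,y paired numeric vectors.
#' @param tail `"two"` or `"one"` (one-sided in the direction of the
#'   observed rho).
#' @return A one-row `test_result` tibble with `estimate` (rho) as the
#'   statistic and `n` the number of complete pairs.
#' @export
spearman_test <- function(x, y, tail = c("two", "one")) {
  tail <- match.arg(tail)
  keep <- complete.cases(x, y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs >= 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("Constant vector: rho undefined.")
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    if (tail == "one") p <- p / 2
  }
  test_result("Spearman rho", rho, p, tail, list(n = n))
}

#' Two-sample t-test, optionally on log-transformed values
#'
#' Thin wrapper around [stats::t.test()] adding the log-transform used for
#' right-skewed concentration data (all values must then be positive) and
#' the one-/two-tailed convention of the other tests (one-tailed: first
#' group mean smaller).
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @param log_transform test on `log(x)`?
#' @param tail `"two"` or `"one"`.
#' @param welch Welch (unequal-variance) test? Default TRUE; FALSE pools.
#' @return A one-row `test_result` tibble (`statistic` = t).
#' @export
t_test <- function(a, b, log_transform = FALSE, tail = c("two", "one"),
                   welch = TRUE) {
  tail <- match.arg(tail)
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2 || length(b) < 2) abort("Each group needs >= 2 values.")
  if (log_transform) {
    bad <- c(which(a <= 0), which(b <= 0) + length(a))
    if (length(bad)) {
      abort(sprintf("Non-positive value(s) at pooled position(s) %s cannot be log-transformed.",
                    paste(bad, collapse = ", ")))
    }
    a <- log(a); b <- log(b)
  }
  ht <- t.test(a, b, var.equal = !welch,
               alternative = if (tail == "one") "less" else "two.sided")
  test_result(if (welch) "Welch t" else "Pooled t",
              unname(ht$statistic), ht$p.value, tail,
              list(n_a = length(a), n_b = length(b)))
}

#' Pearson chi-squared test on a 2 x k contingency table
#'
#' @param table matrix of non-negative counts with two rows.
#' @param correct apply Yates continuity correction (2 x 2 only)?
#'   Default FALSE.
#' @return A one-row `test_result` tibble (`statistic` = X-squared,
#'   `df` column added).
#' @export
chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) != 2 || ncol(table) < 2) {
    abort("`table` must be 2 x k with k >= 2.")
  }
  if (any(table < 0)) abort("Counts must be >= 0.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Degenerate table: a row or column sums to zero.")
  }
  ht <- suppressWarnings(chisq.test(table, correct = correct))
  out <- test_result("Pearson chi-squared", unname(ht$statistic),
                     ht$p.value, "two", list(n = sum(table)))
  out$df <- unname(ht$parameter)
  out
}

#' Geometric mean with a t-based confidence interval
#'
#' gm = exp(mean(log x)); the interval is the exponential of the t interval
#' on the log scale. With zero log-scale spread the interval degenerates to
#' the point.
#'
#' @param x positive numeric values (n >= 2).
#' @param level confidence level.
#' @return A tibble with `gm`, `low`, `high`, `n`, `level`.
#' @examples
#' geometric_mean_ci(c(45, 80, 120, 180))
#' @export
geometric_mean_ci <- function(x, level = 0.95) {
  x <- as.numeric(x[!is.na(x)])
  if (any(x <= 0)) abort("All values must be > 0 for a geometric mean.")
  n <- length(x)
  if (n < 2) abort("Need >= 2 values.")
  lx <- log(x)
  m <- mean(lx)
  se <- sd(lx) / sqrt(n)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * se
  tibble::tibble(gm = exp(m), low = exp(m - half), high = exp(m + half),
                 n = n, level = level)
}

#' Covariate-adjusted logistic regression for one metabolite
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of a binary
#' outcome on a metabolite level plus one adjustment covariate (typically
#' gender), with Wald p-values. Non-convergence and (quasi-)separation are
#' flagged explicitly rather than returned silently.
#'
#' @param outcome binary vector (0/1, logical, or two-level factor).
#' @param metabolite numeric metabolite levels.
#' @param covariate adjustment covariate (numeric or two-level factor).
#' @return A tibble of class `logistic_fit`, one row per term: `term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`; attributes
#'   `converged` and `separation` (logical flags).
#' @export
logistic_adjusted <- function(outcome, metabolite, covariate) {
  if (is.factor(outcome) || is.character(outcome)) {
    outcome <- class_vector(outcome)
  }
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) abort("`outcome` must be binary.")
  if (length(unique(outcome)) < 2) abort("`outcome` has a single class.")
  n <- length(outcome)
  if (n < 10) abort("Need n >= 10 for a stable logistic fit.")
  df <- data.frame(outcome = outcome, metabolite = as.numeric(metabolite),
                   covariate = covariate)
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    glm(outcome ~ metabolite + covariate, family = binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)$coefficients
  separation <- sep_warned || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE) ||
    all(abs(fit$fitted.values - outcome) < 1e-8)
  if (separation) {
    warn("Possible (quasi-)separation: coefficients are unreliable.")
  }
  out <- tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                        std_error = sm[, 2], statistic = sm[, 3],
                        p_value = sm[, 4])
  attr(out, "converged") <- fit$converged
  attr(out, "separation") <- separation
  class(out) <- c("logistic_fit", class(tibble::tibble()))
  out
}
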