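#' @importFrom rlang abort warn inform %||%
#' @importFrom stats cor median sd rnorm rlnorm runif rbinom quantile
#' @importFrom stats pt qt pnorm pchisq t.test chisq.test glm binomial coef
#' @importFrom stats setNames complete.cases predict
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic entry points funnel
# through this so a user-visible seed argument never clobbers the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed and an index, staying inside the
# 32-bit integer range R requires of set.seed().
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 10007) %% 2147483647L)
}

# Column means and sds (n - 1 denominator) without forming a copy per column.
col_means_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  if (n < 2) {
    return(list(means = mu, sds = rep(NA_real_, ncol(X))))
  }
  ss <- colSums(X^2) - n * mu^2
  ss[ss < 0] <- 0
  list(means = mu, sds = sqrt(ss / (n - 1)))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
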