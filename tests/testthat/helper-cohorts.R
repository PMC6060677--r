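# Shared fixture builders. Everything is generated in code at test time.

# Small two-class cohort with designated effect metabolites.
effect_cohort <- function(seed = 1, n = 10, fold = 1.5, n_points = 1500,
                          ...) {
  des <- cohort_design(
    c(case = n, village_control = n),
    n_points = n_points, seed = seed,
    effect_map = list(case = list(
      hippurate = fold, "p-cresol sulphate" = fold,
      "N-methylnicotinamide" = fold)),
    ...)
  simulate_cohort(des)
}

# Null cohort: no class effects at all.
null_cohort <- function(seed = 1, n = 6, n_points = 600, ...) {
  des <- cohort_design(c(case = n, village_control = n),
                       n_points = n_points, seed = seed, ...)
  simulate_cohort(des)
}

# Matrix with one perfectly separating column plus faint noise.
planted_matrix <- function(y, p_noise = 4, noise = 1e-3, seed = 42) {
  with_seed_test(seed, {
    cbind(y, matrix(rnorm(length(y) * p_noise, sd = noise),
                    length(y), p_noise))
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# exhaustive Mann-Whitney null enumeration, independent of the package's
# internal implementation (kept deliberately naive).
enum_mw_p <- function(a, b, tail = "two") {
  pooled <- c(a, b)
  n_a <- length(a)
  u_stat <- function(x, y) {
    s <- 0
    for (xi in x) for (yi in y) {
      s <- s + (xi > yi) + 0.5 * (xi == yi)
    }
    s
  }
  u_obs <- u_stat(a, b)
  combos <- utils::combn(length(pooled), n_a)
  us <- numeric(ncol(combos))
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    us[j] <- u_stat(pooled[idx], pooled[-idx])
  }
  mu <- n_a * length(b) / 2
  if (tail == "one") mean(us <= u_obs) else mean(abs(us - mu) >= abs(u_obs - mu))
}
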