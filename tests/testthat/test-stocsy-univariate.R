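test_that("stocsy equals brute-force column-wise Pearson correlation", {
  with_seed_test(21, {
    X <- matrix(rnorm(10 * 50), 10, 50)
  })
  st <- stocsy(X, driver_index = 17)
  r_oracle <- apply(X, 2, function(col) cor(X[, 17], col))
  cov_oracle <- apply(X, 2, function(col) cov(X[, 17], col))
  expect_equal(st$r, unname(r_oracle), tolerance = 1e-12)
  expect_equal(st$cov, unname(cov_oracle), tolerance = 1e-12)
  expect_equal(st$r[17], 1, tolerance = 1e-12)
})

test_that("stocsy endpoints: anti-correlated column, driver lookup, errors", {
  with_seed_test(22, X <- matrix(rnorm(8 * 5), 8, 5))
  X[, 2] <- -X[, 4]
  sp <- nmr_spectra(X, ppm = c(5, 4, 3, 2, 1))
  st <- stocsy(sp, driver_ppm = 2.1)      # snaps to 2 (column 4)
  expect_equal(attr(st, "driver"), 4L)
  expect_equal(st$r[2], -1, tolerance = 1e-12)
  expect_error(stocsy(sp, driver_ppm = 11), "outside")
  X0 <- X; X0[, 1] <- 5
  expect_error(stocsy(nmr_spectra(X0, c(5, 4, 3, 2, 1)), driver_ppm = 5),
               "zero variance")
  expect_error(stocsy(X[1:2, ], driver_index = 1), ">= 3")
})

test_that("stocsy r agrees with the O-PLS loading r at the top variable", {
  coh <- effect_cohort(seed = 13, n = 10, n_points = 800)
  sp <- pqn_normalize(coh$spectra)$spectra
  y <- class_vector(coh$samples$class_label, positive = "case")
  sc <- scale_uv(sp)
  m <- fit_opls_da(sc$X, y, n_orth = 0, scaling_state = sc$state)
  top <- which.max(abs(m$loading_r))
  st <- stocsy(sp, driver_index = sc$state$kept_columns[top])
  # both are correlations against essentially the same latent direction
  agree <- cor(st$r[sc$state$kept_columns], m$loading_r)
  expect_gt(abs(agree), 0.95)
})

test_that("mann_whitney matches exhaustive enumeration for small groups", {
  out <- mann_whitney(c(1, 2), c(3, 4), tail = "one")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1 / 6, tolerance = 1e-12)

  # all group sizes with n_a + n_b <= 8, including ties
  with_seed_test(31, {
    for (n_a in 2:4) {
      for (n_b in 2:4) {
        if (n_a + n_b > 8) next
        a <- sample(1:4, n_a, replace = TRUE)
        b <- sample(1:4, n_b, replace = TRUE)
        for (tl in c("one", "two")) {
          expect_equal(mann_whitney(a, b, tail = tl)$p_value,
                       enum_mw_p(a, b, tl), tolerance = 1e-12,
                       label = sprintf("n_a=%d n_b=%d %s", n_a, n_b, tl))
        }
      }
    }
  })
})

test_that("mann_whitney symmetry, invariance and approximation accuracy", {
  a <- c(1, 2, 2, 5)
  out <- mann_whitney(a, a)
  expect_equal(out$statistic, length(a)^2 / 2)
  expect_equal(out$p_value, 1)
  # shift invariance
  b <- c(0, 3, 4, 9)
  expect_equal(mann_whitney(a, b)$p_value,
               mann_whitney(a + 100, b + 100)$p_value)
  expect_equal(mann_whitney(a, b)$statistic,
               mann_whitney(a + 100, b + 100)$statistic)
  # normal approximation within 0.02 of exact for continuous n = 5 + 5 draws
  with_seed_test(41, {
    for (i in 1:20) {
      x <- rnorm(5)
      y <- rnorm(5)
      p_ex <- mann_whitney(x, y, tail = "two", exact_max = 10)$p_value
      p_ap <- mann_whitney(x, y, tail = "two", exact_max = 0)$p_value
      expect_lt(abs(p_ex - p_ap), 0.02)
    }
  })
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("spearman_test handles monotone, reversed and tied data", {
  out <- spearman_test(c(1, 2, 3), c(1, 4, 9))
  expect_equal(out$statistic, 1)
  expect_equal(spearman_test(c(1, 2, 3), c(9, 4, 1))$statistic, -1)
  with_seed_test(51, {
    x <- sample(1:5, 12, replace = TRUE)
    y <- x + sample(0:2, 12, replace = TRUE)
  })
  rho_oracle <- cor(rank(x), rank(y))   # midrank-Pearson, computed directly
  out <- spearman_test(x, y)
  expect_equal(out$statistic, rho_oracle, tolerance = 1e-12)
  # untied data: agrees with the standard library implementation
  ref <- cor.test(c(3, 1, 4, 2, 5), c(2, 1, 5, 4, 3), method = "spearman")
  expect_equal(spearman_test(c(3, 1, 4, 2, 5), c(2, 1, 5, 4, 3))$statistic,
               unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_test(c(1, 1, 1), 1:3), "Constant")
  expect_error(spearman_test(1:2, 1:2), ">= 3")
})

test_that("t_test covers identity, log-transform and the pooled closed form", {
  a <- c(1, 10, 100)
  expect_equal(t_test(a, a)$statistic, 0)
  expect_equal(t_test(a, a)$p_value, 1)
  expect_equal(t_test(a, a, log_transform = TRUE)$statistic, 0)
  expect_error(t_test(c(-1, 2, 3), a, log_transform = TRUE), "Non-positive")

  x <- c(5.1, 4.8, 5.6, 5.3); y <- c(4.2, 4.5, 4.0, 4.7)
  out <- t_test(x, y, welch = FALSE)
  # textbook pooled two-sample t computed from first principles
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(out$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * pt(-abs(t_oracle), df = 6), tolerance = 1e-12)
  # one-tailed convention: first group smaller
  expect_lt(t_test(y, x, tail = "one")$p_value, 0.05)
})

test_that("chi_square matches the closed form and scales homogeneously", {
  flat <- chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  tab <- matrix(c(8, 1, 2, 9), 2)   # [[8,2],[1,9]] in row form
  out <- chi_square(tab)
  # hand computation: sum (O - E)^2 / E
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(out$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(out$df, 1)
  # scaling all counts by c scales the statistic by c
  out3 <- chi_square(3 * tab)
  expect_equal(out3$statistic, 3 * out$statistic, tolerance = 1e-12)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "Degenerate")
})

test_that("geometric_mean_ci matches an independent log-scale t interval", {
  out <- geometric_mean_ci(c(1, 100))
  expect_equal(out$gm, 10, tolerance = 1e-12)

  allc <- geometric_mean_ci(rep(3.5, 6))
  expect_equal(allc$gm, 3.5)
  expect_equal(allc$low, 3.5)
  expect_equal(allc$high, 3.5)

  x <- c(45, 80, 120, 180, 60)
  out <- geometric_mean_ci(x)
  lx <- log(x)
  half <- qt(0.975, 4) * sd(lx) / sqrt(5)
  expect_equal(out$low, exp(mean(lx) - half), tolerance = 1e-12)
  expect_equal(out$high, exp(mean(lx) + half), tolerance = 1e-12)
  expect_error(geometric_mean_ci(c(1, -2)), "> 0")
})

test_that("logistic_adjusted matches a Newton-solver oracle on a fixed toy", {
  with_seed_test(62, {
    n <- 40
    met <- rnorm(n)
    cov_ <- rbinom(n, 1, 0.5)
    eta <- -0.3 + 1.0 * met + 0.5 * cov_
    out <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  })
  fit <- logistic_adjusted(out, met, cov_)
  # independent Newton-Raphson on the log-likelihood
  Xd <- cbind(1, met, cov_)
  beta <- rep(0, 3)
  for (i in 1:50) {
    p <- 1 / (1 + exp(-drop(Xd %*% beta)))
    W <- p * (1 - p)
    beta <- beta + solve(t(Xd) %*% (Xd * W), t(Xd) %*% (out - p))
  }
  expect_equal(fit$estimate, drop(beta), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_false(attr(fit, "separation"))

  # covariate identical to the outcome: separation must be flagged
  expect_warning(fit_sep <- logistic_adjusted(out, met, out), "separation")
  expect_true(attr(fit_sep, "separation"))
})

test_that("logistic_adjusted on pure noise gives small coefficients", {
  betas <- vapply(1:10, function(s) {
    with_seed_test(200 + s, {
      out <- rep(c(0, 1), each = 15)
      met <- rnorm(30)
      cov_ <- rbinom(30, 1, 0.5)
    })
    fit <- suppressWarnings(logistic_adjusted(out, met, cov_))
    fit$estimate[fit$term == "metabolite"]
  }, numeric(1))
  expect_lt(median(abs(betas)), 1)
})

test_that("univariate tests are invariant to sample order", {
  with_seed_test(71, {
    a <- rnorm(8); b <- rnorm(9) + 0.5
    perm_a <- sample(a); perm_b <- sample(b)
  })
  expect_equal(mann_whitney(a, b)$p_value,
               mann_whitney(perm_a, perm_b)$p_value)
  expect_equal(t_test(a, b)$p_value, t_test(perm_a, perm_b)$p_value)
})
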