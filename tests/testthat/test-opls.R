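centred <- function(X) sweep(X, 2, colMeans(X))

test_that("one-component PLS1 equals the closed-form solution on a toy matrix", {
  X <- centred(matrix(c(1, 2, 0, 4, 3,
                        0, 1, 2, 2, 5,
                        2, 0, 1, 3, 1), 5, 3))
  y <- c(0, 0, 1, 1, 1)
  m <- fit_pls_da(X, y, 1)
  # direct matrix arithmetic oracle
  yc <- y - mean(y)
  w <- drop(crossprod(X, yc)); w <- w / sqrt(sum(w^2))
  t_ <- drop(X %*% w)
  if (sum(t_ * yc) < 0) { w <- -w; t_ <- -t_ }
  expect_equal(m$W[, 1], w, tolerance = 1e-12)
  expect_equal(m$T[, 1], t_, tolerance = 1e-12)
  expect_equal(m$C[1], sum(yc * t_) / sum(t_^2), tolerance = 1e-12)
  expect_equal(m$P[, 1], drop(crossprod(X, t_)) / sum(t_^2), tolerance = 1e-12)
})

test_that("a perfectly discriminating column gives R2Y = 1", {
  y <- rep(c(0, 1), each = 4)
  X <- centred(cbind(y))
  m <- fit_pls_da(X, y, 1)
  expect_equal(tail(m$r2y, 1), 1, tolerance = 1e-12)
})

test_that("flipping the class coding flips score signs only", {
  coh <- null_cohort(seed = 4, n = 5, n_points = 200)
  sc <- scale_uv(coh$spectra)
  y <- class_vector(coh$samples$class_label, positive = "case")
  m1 <- fit_opls_da(sc$X, y, n_orth = 1)
  m2 <- fit_opls_da(sc$X, 1 - y, n_orth = 1)
  expect_equal(m2$t, -m1$t, tolerance = 1e-10)
  expect_equal(m2$w, -m1$w, tolerance = 1e-10)
  expect_equal(m2$r2y, m1$r2y, tolerance = 1e-10)
  # fitted class values agree after recoding
  expect_equal(m2$t * m2$c + m2$y_mean, 1 - (m1$t * m1$c + m1$y_mean),
               tolerance = 1e-10)
})

test_that("n_orth = 0 O-PLS-DA is exactly one-component PLS-DA", {
  coh <- null_cohort(seed = 8, n = 6, n_points = 300)
  sc <- scale_uv(coh$spectra)
  y <- class_vector(coh$samples$class_label)
  pls <- fit_pls_da(sc$X, y, 1)
  opls <- fit_opls_da(sc$X, y, n_orth = 0)
  expect_equal(opls$w, pls$W[, 1], tolerance = 1e-10)
  expect_equal(opls$t, pls$T[, 1], tolerance = 1e-10)
  expect_equal(opls$p, pls$P[, 1], tolerance = 1e-10)
  expect_equal(opls$c, pls$C[1], tolerance = 1e-10)
  expect_equal(opls$r2y, tail(pls$r2y, 1), tolerance = 1e-10)
  expect_equal(opls$r2x, tail(pls$r2x, 1), tolerance = 1e-10)
})

test_that("orthogonal scores are orthogonal to the centred class dummy", {
  coh <- effect_cohort(seed = 5, n = 8, n_points = 500)
  sc <- scale_uv(coh$spectra)
  y <- class_vector(coh$samples$class_label, positive = "case")
  m <- fit_opls_da(sc$X, y, n_orth = 3)
  yc <- y - mean(y)
  for (k in seq_len(m$n_orth)) {
    t_o <- m$T_orth[, k]
    expect_lt(abs(sum(t_o * yc)) / (sqrt(sum(t_o^2)) * sqrt(sum(yc^2))), 1e-8)
    # also orthogonal to the predictive score
    expect_lt(abs(sum(t_o * m$t)) / (sqrt(sum(t_o^2)) * sqrt(sum(m$t^2))),
              1e-8)
  }
})

test_that("one orthogonal component equals PLS on the manually deflated matrix", {
  coh <- effect_cohort(seed = 6, n = 8, n_points = 400)
  sc <- scale_uv(coh$spectra)
  y <- class_vector(coh$samples$class_label, positive = "case")
  m <- fit_opls_da(sc$X, y, n_orth = 1)
  # oracle: deflate by hand, then closed-form PLS1 on the filtered matrix
  yc <- y - mean(y)
  w <- drop(crossprod(sc$X, yc)); w <- w / sqrt(sum(w^2))
  t_ <- drop(sc$X %*% w)
  p <- drop(crossprod(sc$X, t_)) / sum(t_^2)
  w_o <- p - sum(w * p) * w; w_o <- w_o / sqrt(sum(w_o^2))
  t_o <- drop(sc$X %*% w_o)
  p_o <- drop(crossprod(sc$X, t_o)) / sum(t_o^2)
  Xf <- sc$X - tcrossprod(t_o, p_o)
  ref <- fit_pls_da(Xf, y, 1)
  expect_equal(m$t, ref$T[, 1], tolerance = 1e-10)
  expect_equal(m$w, ref$W[, 1], tolerance = 1e-10)
})

test_that("R2Y is monotonically non-decreasing in PLS components", {
  coh <- effect_cohort(seed = 7, n = 7, n_points = 300)
  sc <- scale_uv(coh$spectra)
  y <- class_vector(coh$samples$class_label)
  m <- fit_pls_da(sc$X, y, 5)
  expect_true(all(diff(m$r2y) >= -1e-12))
})

test_that("predict reproduces training scores and handles degenerate input", {
  coh <- effect_cohort(seed = 9, n = 6, n_points = 300)
  sc <- scale_uv(coh$spectra)
  y <- class_vector(coh$samples$class_label, positive = "case")
  m <- fit_opls_da(sc$X, y, n_orth = 2)
  pr <- predict(m, sc$X)
  expect_equal(pr$t, m$t, tolerance = 1e-10)
  expect_equal(pr$t_orth, m$T_orth, tolerance = 1e-10)
  # zero matrix predicts the training class mean
  pr0 <- predict(m, matrix(0, 3, ncol(sc$X)))
  expect_equal(pr0$y_hat, rep(mean(y), 3), tolerance = 1e-12)
  expect_error(predict(m, sc$X[, 1:5]), "columns")
})

test_that("held-out predictions match a hand-rolled matrix oracle", {
  with_seed_test(31, {
    X <- matrix(rnorm(6 * 4), 6, 4)
    y <- c(0, 0, 0, 1, 1, 1)
    X[, 1] <- X[, 1] + 2 * y
  })
  tr <- c(1, 2, 4, 5); te <- c(3, 6)
  sc <- scale_uv(X[tr, ])
  m <- fit_opls_da(sc$X, y[tr], n_orth = 1)
  Xte <- apply_scaling(X[te, ], sc$state)
  pr <- predict(m, Xte)
  # oracle: apply the stored filter and projection by explicit arithmetic
  Xf <- Xte - (Xte %*% m$W_orth[, 1]) %*% t(m$P_orth[, 1])
  t_new <- drop(Xf %*% m$w)
  expect_equal(pr$t, t_new, tolerance = 1e-12)
  expect_equal(pr$y_hat, t_new * m$c + mean(y[tr]), tolerance = 1e-12)
})

test_that("back-scaled loadings recover covariance scale and brute-force r", {
  coh <- effect_cohort(seed = 10, n = 8, n_points = 400)
  sc <- scale_uv(coh$spectra)
  y <- class_vector(coh$samples$class_label, positive = "case")
  m <- fit_opls_da(sc$X, y, n_orth = 1, scaling_state = sc$state)
  prof <- backscaled_loadings(m)
  expect_equal(nrow(prof), length(sc$state$kept_columns))
  expect_equal(prof$backscaled,
               m$p * sc$state$column_sds[sc$state$kept_columns],
               tolerance = 1e-12)
  # brute-force per-column Pearson correlation oracle
  r_oracle <- apply(sc$X, 2, function(col) cor(m$t, col))
  expect_equal(prof$r, unname(r_oracle), tolerance = 1e-12)
  expect_true(all(abs(prof$r) <= 1 + 1e-12))
  expect_error(backscaled_loadings(fit_opls_da(sc$X, y, 0)), "scaling state")
})

test_that("a lone perfectly discriminating column has |r| = 1 and dropped columns vanish", {
  y <- rep(c(0, 1), each = 5)
  X <- cbind(2 * y + 1, 7)   # one informative column, one constant (sd 0)
  sc <- scale_uv(X)
  m <- fit_opls_da(sc$X, y, 0, scaling_state = sc$state)
  prof <- backscaled_loadings(m)
  expect_equal(nrow(prof), 1L)          # the constant column is absent
  expect_equal(prof$variable, 1L)
  expect_equal(abs(prof$r[1]), 1, tolerance = 1e-12)
})

test_that("single-class input and rank violations are rejected", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_pls_da(X, rep(1, 5), 1), "single")
  expect_error(fit_pls_da(centred(X), c(0, 0, 1, 1, 1), 10), "rank")
  expect_error(fit_opls_da(centred(X), c(0, 0, 1, 1, 1), n_orth = 8), "rank")
})

test_that("predictive scores agree with an independent PLS implementation", {
  coh <- effect_cohort(seed = 12, n = 8, n_points = 300)
  sc <- scale_uv(coh$spectra)
  y <- class_vector(coh$samples$class_label, positive = "case")
  ours <- fit_pls_da(sc$X, y, 1)
  ref <- mixOmics::pls(sc$X, y - mean(y), ncomp = 1, scale = FALSE,
                       mode = "regression")
  expect_gt(abs(cor(ours$T[, 1], ref$variates$X[, 1])), 1 - 1e-8)
})
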