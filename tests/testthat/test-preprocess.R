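test_that("exclude_regions removes exactly the contained columns", {
  sp <- nmr_spectra(matrix(1:6, 2, 3, byrow = TRUE), ppm = c(5.0, 4.8, 4.6))
  out <- exclude_regions(sp, region_set(c(4.7, 4.9)))
  expect_equal(out$ppm, c(5.0, 4.6))
  expect_equal(ncol(out$intensities), 2L)
  expect_equal(nrow(out$intensities), 2L)

  # empty region set is the identity
  ident <- exclude_regions(sp, region_set())
  expect_equal(ident$intensities, sp$intensities)

  expect_error(exclude_regions(sp, region_set(c(0, 10))), "every")
  expect_error(region_set(c(5, 4)), "low")
})

test_that("pqn quotients satisfy the defining identities", {
  ref <- c(1, 2, 3, 4, 5)
  sp <- nmr_spectra(rbind(ref, 2 * ref, 0.5 * ref), ppm = 5:1,
                    sample_ids = c("r", "double", "half"))
  pq <- pqn_normalize(sp, reference = ref)
  expect_equal(unname(pq$quotients), c(1, 2, 0.5))
  expect_equal(pq$spectra$intensities["double", ], ref, ignore_attr = TRUE)
  # reference normalised against itself has quotient 1
  expect_equal(unname(pqn_normalize(sp, reference = "r")$quotients[1]), 1)
})

test_that("pqn is scale-equivariant against a fixed reference", {
  coh <- null_cohort(seed = 5, n = 4)
  ref <- apply(coh$spectra$intensities, 2, median)
  pq1 <- pqn_normalize(coh$spectra, reference = ref)
  c_ <- 3.7
  scaled <- nmr_spectra(c_ * coh$spectra$intensities, coh$spectra$ppm,
                        sample_ids(coh$spectra))
  pq2 <- pqn_normalize(scaled, reference = ref)
  expect_equal(pq2$quotients, c_ * pq1$quotients, tolerance = 1e-12)
  expect_equal(pq2$spectra$intensities, pq1$spectra$intensities,
               tolerance = 1e-12)
  # with the data-derived median reference the quotients are scale-invariant
  pq3 <- pqn_normalize(scaled)
  expect_equal(pq3$quotients, pqn_normalize(coh$spectra)$quotients,
               tolerance = 1e-12)
})

test_that("pqn recovers simulated dilution factors against ground truth", {
  des <- cohort_design(c(case = 20, village_control = 20), n_points = 3000,
                       dilution_sigma = 0.4, biological_cv = 0,
                       jitter_sd_ppm = 0, noise_sd = 0.002,
                       baseline_amplitude = 0, seed = 21)
  coh <- simulate_cohort(des)
  pq <- pqn_normalize(exclude_regions(coh$spectra, water_region()))
  truth <- coh$truth$dilution_factors
  expect_gt(cor(pq$quotients, truth), 0.99)
  # quotients are defined up to the reference's overall scale: compare
  # median-normalised relative dilution
  q_rel <- pq$quotients / median(pq$quotients)
  d_rel <- truth / median(truth)
  expect_lt(median(abs(q_rel / d_rel - 1)), 0.02)
})

test_that("a sample with no usable columns is reported by name", {
  sp <- nmr_spectra(rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(0, 0, 0)),
                    ppm = c(3, 2, 1))
  expect_error(pqn_normalize(sp), "Zero quotient.*c")
})

test_that("scale_uv centres, scales with n-1 SD and back-transforms exactly", {
  X <- cbind(c(1, 3), c(5, 2), c(2, 2))
  sc <- scale_uv(X)
  expect_equal(sc$X[, 1], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # constant column dropped and recorded
  expect_equal(sc$state$kept_columns, c(1L, 2L))
  expect_equal(setdiff(seq_len(3), sc$state$kept_columns), 3L)
  # exact bijection on kept columns
  expect_equal(unscale_uv(sc$X, sc$state), X[, 1:2], tolerance = 1e-12)
  expect_error(scale_uv(matrix(1, 3, 2)), "zero variance")
})

test_that("apply_scaling reuses training means/sds on new data", {
  coh <- null_cohort(seed = 2, n = 4)
  X <- coh$spectra$intensities
  sc <- scale_uv(X[1:6, ])
  expect_equal(apply_scaling(X[1:6, ], sc$state), sc$X, tolerance = 1e-12)
  expect_error(apply_scaling(X[, 1:10], sc$state), "Column count")
})
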