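# Random-effects model selection, family inference and session averaging.

test_that("symmetric evidence yields uniform model probabilities", {
  F <- matrix(0, 12, 4) # identical columns
  res <- rfx_bms(F, seed = 1, n_samples = 2e5)
  expect_equal(sum(res$expected_p), 1, tolerance = 1e-9)
  expect_equal(unname(res$expected_p), rep(0.25, 4), tolerance = 1e-9)
  expect_equal(unname(res$exceedance_p), rep(0.25, 4), tolerance = 0.01)
  expect_equal(sum(res$exceedance_p), 1, tolerance = 1e-9)
})

test_that("a dominant model attains near-certain exceedance", {
  set.seed(2)
  F <- matrix(rnorm(10 * 4), 10, 4)
  F[, 3] <- F[, 3] + 10
  res <- rfx_bms(F, seed = 1, n_samples = 2e5)
  expect_gt(res$exceedance_p[3], 0.99)
  expect_equal(which.max(res$expected_p), 3L)
})

test_that("model selection is equivariant under model reordering", {
  set.seed(3)
  F <- matrix(rnorm(8 * 4), 8, 4) + rep(c(0, 1, 2, 0.5), each = 8)
  perm <- c(3, 1, 4, 2)
  r1 <- rfx_bms(F, seed = 9, n_samples = 2e5)
  r2 <- rfx_bms(F[, perm], seed = 9, n_samples = 2e5)
  expect_equal(unname(r2$alpha), unname(r1$alpha[perm]), tolerance = 1e-9)
  expect_equal(unname(r2$expected_p), unname(r1$expected_p[perm]),
               tolerance = 1e-9)
  expect_equal(unname(r2$exceedance_p), unname(r1$exceedance_p[perm]),
               tolerance = 0.01)
})

test_that("adding a per-subject constant leaves the posterior unchanged", {
  set.seed(4)
  F <- matrix(rnorm(9 * 5), 9, 5)
  r1 <- rfx_bms(F, seed = 7, n_samples = 1e5)
  r2 <- rfx_bms(F + 312.7, seed = 7, n_samples = 1e5)
  expect_equal(r1$alpha, r2$alpha, tolerance = 1e-9)
  expect_equal(r1$exceedance_p, r2$exceedance_p, tolerance = 1e-9)
})

test_that("exceedance sampling error is small at many draws", {
  set.seed(5)
  F <- matrix(rnorm(10 * 4, sd = 2), 10, 4)
  r1 <- rfx_bms(F, seed = 1, n_samples = 1e6)
  r2 <- rfx_bms(F, seed = 2, n_samples = 1e6)
  expect_lt(max(abs(r1$exceedance_p - r2$exceedance_p)), 0.005)
})

test_that("non-finite evidence is rejected", {
  F <- matrix(0, 4, 3)
  F[2, 2] <- NA
  expect_error(rfx_bms(F), "finite")
})

test_that("equal-size families split symmetric evidence evenly", {
  F <- matrix(0, 10, 8)
  res <- family_bms(F, partition = list(a = 1:4, b = 5:8), seed = 3,
                    n_samples = 2e5)
  expect_equal(unname(res$family_expected_p), c(0.5, 0.5),
               tolerance = 0.02)
  expect_equal(unname(res$family_exceedance_p), c(0.5, 0.5),
               tolerance = 0.05)
})

test_that("family-size imbalance is corrected through the prior", {
  F <- matrix(0, 10, 8) # uninformative evidence
  res <- family_bms(F, partition = list(big = 1:6, small = 7:8), seed = 3,
                    n_samples = 2e5)
  expect_equal(unname(res$family_expected_p), c(0.5, 0.5),
               tolerance = 0.02)
  expect_equal(unname(res$family_exceedance_p), c(0.5, 0.5),
               tolerance = 0.05)
  expect_error(family_bms(F, partition = list(a = 1:8, b = integer(0))),
               "empty")
  expect_error(family_bms(F, partition = list(a = 1:5, b = 5:8)),
               "disjoint")
})

test_that("evidence from the intrinsic family drives its exceedance high", {
  set.seed(6)
  for (k in 1:10) {
    F <- matrix(rnorm(12 * 8), 12, 8)
    F[, 5:8] <- F[, 5:8] + 4 # generating model sits in the 5-8 family
    res <- family_bms(F, seed = k, n_samples = 1e5)
    expect_gt(res$family_exceedance_p[["intrinsic"]], 0.9)
  }
})

test_that("session averaging honours evidence weights", {
  spec <- dcm_model_space()$model8
  np <- nrow(dcm_par_index(spec))
  mk_fit <- function(theta1, F) {
    th <- rep(theta1, np)
    structure(list(theta = setNames(th, dcm_par_index(spec)$name),
                   Sigma = diag(0.01, np), F = F, spec = spec),
              class = "dcm_fit")
  }
  # identical fits average to themselves
  fits <- lapply(1:4, function(i) mk_fit(0.3, -100))
  bma <- bma_sessions(fits)
  expect_equal(unname(bma$theta), rep(0.3, np), tolerance = 1e-12)
  expect_equal(unname(bma$weights), rep(0.25, 4))
  # identical posteriors also average to themselves under precision mode
  expect_equal(unname(bma_sessions(fits, "precision")$theta),
               rep(0.3, np), tolerance = 1e-9)
  # under evidence weighting one dominant session takes all the weight
  fits2 <- list(mk_fit(0.1, -100), mk_fit(0.9, -80))
  bma2 <- bma_sessions(fits2, weighting = "evidence")
  expect_lt(max(abs(bma2$theta - 0.9)), 1e-6)
  # precision mode with equal uncertainties treats sessions evenly
  expect_equal(unname(bma_sessions(fits2, "precision")$theta),
               rep(0.5, np), tolerance = 1e-9)
  # equal evidence averages arithmetically
  fits3 <- lapply(c(0.1, 0.2, 0.3, 0.4), function(v) mk_fit(v, -50))
  bma3 <- bma_sessions(fits3, weighting = "evidence")
  expect_equal(unname(bma3$theta), rep(0.25, np), tolerance = 1e-12)
  expect_equal(unname(bma_sessions(fits3, "precision")$theta),
               rep(0.25, np), tolerance = 1e-9)
  expect_equal(unname(bma_sessions(fits3, weighting = "equal")$theta),
               rep(0.25, np), tolerance = 1e-12)
  # mixed specifications are rejected
  f_other <- mk_fit(0.1, -50)
  f_other$spec <- dcm_model_space()$model1
  f_other$theta <- f_other$theta[1:10]
  expect_error(bma_sessions(list(fits3[[1]], f_other)), "specification")
})
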