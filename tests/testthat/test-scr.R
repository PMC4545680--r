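# Canonical skin-conductance impulse response, forward generator and GLM.

test_that("canonical impulse response is causal, peaks on time, decays", {
  expect_equal(canonical_scrf(0), 0)
  expect_equal(canonical_scrf(c(-1, -0.1)), c(0, 0))
  grid <- seq(0, 40, by = 0.001)
  v <- canonical_scrf(grid)
  expect_equal(grid[which.max(v)], 3.5, tolerance = 0.005)
  expect_equal(max(v), 1, tolerance = 1e-6)
  expect_lt(canonical_scrf(3.5 + 20), 0.2)
  # configurable peak
  v7 <- canonical_scrf(grid, peak_time = 7)
  expect_equal(grid[which.max(v7)], 7, tolerance = 0.005)
})

test_that("generator produces a flat trace with no events and no noise", {
  sched <- test_schedule()
  tr <- generate_scr(sched, amplitudes = list(all = 0, pain = 0,
                                              trial_sd = 0),
                     noise_sd = 0, baseline = 2,
                     drift = list(sin_amp = 0, sin_period = 300,
                                  linear = 0))[[1]]
  expect_true(all(tr$samples == 2))
})

test_that("a single event reproduces the scaled impulse response", {
  sched <- test_schedule()
  fs <- 100
  d <- build_scr_design(sched, 1, fs, single_trial = 1)
  n <- nrow(d)
  kern <- canonical_scrf(seq_len(round(40 * fs)) / fs)
  oracle <- convolve_oracle(sched$onset[1], kern, n, fs)
  expect_lt(max(abs(d[, "trial"] - oracle)), 1e-9)
})

test_that("design columns match an independent convolution oracle", {
  sched <- test_schedule()
  fs <- 50
  d <- build_scr_design(sched, 1, fs)
  n <- nrow(d)
  kern <- canonical_scrf(seq_len(round(40 * fs)) / fs)
  s <- sched[sched$run == 1, ]
  expect_lt(max(abs(d[, "all_images"] -
                      convolve_oracle(s$onset, kern, n, fs))), 1e-9)
  expect_lt(max(abs(d[, "painful_images"] -
                      convolve_oracle(s$onset[s$painful], kern, n, fs))),
            1e-9)
  # painful column vanishes when no painful trials are modelled
  s_nopain <- sched
  s_nopain$painful <- FALSE
  d2 <- build_scr_design(s_nopain, 1, fs)
  expect_true(all(d2[, "painful_images"] == 0))
})

test_that("traces are reproducible under a seed and reject low rates", {
  sched <- test_schedule()
  a <- generate_scr(sched, seed = 3)[[1]]
  b <- generate_scr(sched, seed = 3)[[1]]
  expect_identical(a$samples, b$samples)
  expect_error(generate_scr(sched, sampling_rate = 0.5), "sampling rate")
})

test_that("whole-run betas are recovered exactly without noise", {
  sched <- test_schedule()
  tr <- generate_scr(sched, amplitudes = list(all = 1, pain = 0.5,
                                              trial_sd = 0),
                     noise_sd = 0, baseline = 0,
                     drift = list(sin_amp = 0, sin_period = 300,
                                  linear = 0))[[1]]
  d <- build_scr_design(sched, 1, 100)
  f <- fit_scr_glm(tr, d, filter = FALSE, normalize = "none")
  expect_equal(unname(f$betas), c(1, 0.5), tolerance = 1e-8)
  # band-pass applied to both sides leaves recovery within 5%
  f2 <- fit_scr_glm(tr, d, filter = TRUE, normalize = "none")
  expect_lt(max(abs(f2$betas - c(1, 0.5)) / c(1, 0.5)), 0.05)
})

test_that("white-noise traces give betas centred on zero", {
  sched <- test_schedule()
  fs <- 25
  d <- build_scr_design(sched, 1, fs)
  n <- nrow(d)
  set.seed(31)
  betas <- t(vapply(1:200, function(k) {
    tr <- structure(list(samples = rnorm(n), sampling_rate = fs, run = 1,
                         onsets = sched$onset), class = "scr_trace")
    fit_scr_glm(tr, d, filter = FALSE, normalize = "none")$betas
  }, numeric(2)))
  se <- apply(betas, 2, sd) / sqrt(nrow(betas))
  expect_lt(abs(mean(betas[, 1])), 3 * se[1])
  expect_lt(abs(mean(betas[, 2])), 3 * se[2])
})

test_that("normalised betas are invariant to trace rescaling", {
  sched <- test_schedule()
  tr <- generate_scr(sched, seed = 6)[[1]]
  tr10 <- tr
  tr10$samples <- tr$samples * 10
  d <- build_scr_design(sched, 1, 100)
  f1 <- fit_scr_glm(tr, d)
  f2 <- fit_scr_glm(tr10, d)
  expect_equal(f1$betas, f2$betas, tolerance = 1e-8)
})

test_that("single-trial betas recover per-trial amplitudes", {
  sched <- test_schedule()
  tr <- generate_scr(sched, amplitudes = list(all = 1, pain = 0.5,
                                              trial_sd = 0.25),
                     noise_sd = 0.05, seed = 8)[[1]]
  st <- single_trial_scr_betas(list(tr), sched)
  expect_equal(nrow(st), 64L)
  expect_equal(st$trial, 1:64)
  amp <- attr(tr, "trial_amplitudes")
  expect_gt(cor(st$beta, amp), 0.9)
  # one deviant trial is ranked highest without noise
  amp2 <- list(all = 0.5, pain = 0, trial_sd = 0)
  tr2 <- generate_scr(sched, amplitudes = amp2, noise_sd = 0, baseline = 0,
                      drift = list(sin_amp = 0, sin_period = 300,
                                   linear = 0), seed = 1)[[1]]
  # double the amplitude of trial 20 manually
  fs <- tr2$sampling_rate
  kern <- canonical_scrf(seq_len(round(40 * fs)) / fs)
  i0 <- round(sched$onset[20] * fs) + 1
  idx <- i0:min(length(tr2$samples), i0 + length(kern) - 1)
  tr2$samples[idx] <- tr2$samples[idx] + 0.5 * kern[seq_along(idx)]
  st2 <- single_trial_scr_betas(list(tr2), sched, filter = FALSE,
                                normalize = "none")
  expect_equal(which.max(st2$beta), 20L)
  expect_gt(st2$beta[20], max(st2$beta[-20]) + 0.2)
})

test_that("rank-deficient designs are reported with the offending columns", {
  sched <- test_schedule()
  tr <- generate_scr(sched, seed = 2)[[1]]
  d <- build_scr_design(sched, 1, 100)
  dd <- cbind(d, dup = d[, "all_images"])
  attr(dd, "sampling_rate") <- 100
  expect_error(fit_scr_glm(tr, dd), "collinear")
})
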