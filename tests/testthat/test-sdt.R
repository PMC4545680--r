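# The behavioral generator and the signal-detection scoring are tested
# against each other and against a brute-force criterion-locating oracle.

test_that("zero sensitivity gives equal hit and false-alarm rates", {
  sched <- generate_schedule(n_runs = 25, seed = 1) # 1600 trials
  resp <- do.call(rbind, lapply(1:63, function(k) {
    generate_behavior(sched, dprime = 0, criterion = 0.3, seed = k)
  })) # ~1e5 trials
  r <- tabulate_rates(resp)
  expect_lt(abs(r$hit - r$false_alarm), 0.01)
})

test_that("generated rates converge to the inverse-normal targets", {
  # targets: the ASD group's printed mean hit/false-alarm rates
  target <- c(hit = 0.85, fa = 0.11)
  dprime <- qnorm(target["hit"]) - qnorm(target["fa"]) # 2.263
  crit <- criterion_for_hit_rate(dprime, target["hit"])
  sched <- generate_schedule(n_runs = 25, seed = 2)
  resp <- do.call(rbind, lapply(1:63, function(k) {
    generate_behavior(sched, dprime, crit, seed = 100 + k)
  }))
  r <- tabulate_rates(resp)
  expect_lt(abs(r$hit - 0.85), 0.01)
  expect_lt(abs(r$false_alarm - 0.11), 0.01)
})

test_that("response counts partition the trials", {
  sched <- test_schedule()
  resp <- generate_behavior(sched, 2, 0.1, seed = 5)
  r <- tabulate_rates(resp)
  expect_equal(r$n_signal, 32L)
  expect_equal(r$n_noise, 32L)
  expect_equal(r$hit + r$miss, 1)
  expect_equal(r$false_alarm + r$correct_rejection, 1)
  # missing responses are excluded and counted
  resp2 <- generate_behavior(sched, 2, 0.1, seed = 5, p_miss_response = 0.2)
  r2 <- tabulate_rates(resp2)
  expect_equal(r2$n_signal + r2$n_noise + r2$n_missing, 64L)
  expect_gt(r2$n_missing, 0L)
})

test_that("rate tabulation is exact arithmetic", {
  resp <- data.frame(
    painful = rep(c(TRUE, FALSE), c(128, 128)),
    response = c(rep("pain", 109), rep("no_pain", 19),
                 rep("pain", 20), rep("no_pain", 108)))
  r <- tabulate_rates(resp)
  expect_equal(r$hit, 109 / 128)
  expect_equal(round(r$hit, 4), 0.8516)
  all_pain <- data.frame(painful = c(TRUE, FALSE),
                         response = c("pain", "pain"))
  r2 <- tabulate_rates(all_pain)
  expect_equal(r2$hit, 1)
  expect_equal(r2$false_alarm, 1)
  expect_error(tabulate_rates(data.frame(painful = TRUE,
                                         response = "pain")),
               "noise")
})

test_that("d-prime and beta match the brute-force oracle on a grid", {
  hs <- seq(0.55, 0.98, length.out = 10)
  fs <- seq(0.02, 0.45, length.out = 5)
  for (h in hs) for (f in fs) {
    r <- rate_table(h, f)
    o <- sdt_oracle(h, f)
    expect_lt(abs(compute_dprime(r) - o$d_prime), 1e-6)
    b <- compute_beta(r)
    expect_lt(abs(b$beta - o$beta), 1e-6)
    expect_lt(abs(b$criterion_c - o$criterion_c), 1e-6)
  }
})

test_that("printed group rates give the oracle's sensitivity and bias", {
  # ASD row: hit 0.85, false alarm 0.11; control row: 0.94, 0.07
  for (hf in list(c(0.85, 0.11), c(0.94, 0.07))) {
    r <- rate_table(hf[1], hf[2])
    o <- sdt_oracle(hf[1], hf[2])
    expect_equal(compute_dprime(r), o$d_prime, tolerance = 1e-8)
    expect_equal(compute_beta(r)$beta, o$beta, tolerance = 1e-8)
  }
  expect_equal(compute_dprime(rate_table(0.85, 0.11)),
               qnorm(0.85) - qnorm(0.11))
})

test_that("degenerate and symmetric rate tables behave as defined", {
  expect_equal(compute_dprime(rate_table(0.5, 0.5)), 0)
  expect_equal(compute_beta(rate_table(0.84, 0.16))$beta, 1,
               tolerance = 1e-12)
  expect_equal(compute_dprime(rate_table(0.3, 0.3)), 0)
  expect_equal(compute_beta(rate_table(0.3, 0.3))$beta, 1)
})

test_that("d-prime is monotone in hit and false-alarm rates", {
  hs <- seq(0.5, 0.95, by = 0.05)
  d_h <- vapply(hs, function(h) compute_dprime(rate_table(h, 0.1)),
                numeric(1))
  expect_true(all(diff(d_h) > 0))
  fs <- seq(0.05, 0.5, by = 0.05)
  d_f <- vapply(fs, function(f) compute_dprime(rate_table(0.9, f)),
                numeric(1))
  expect_true(all(diff(d_f) < 0))
})

test_that("extreme rates error uncorrected and are corrected on request", {
  r <- rate_table(1, 0.1, n_signal = 32, n_noise = 32)
  expect_equal(compute_dprime(r), Inf) # naive formula
  d <- compute_dprime(r, correct_extremes = TRUE)
  expect_true(is.finite(d))
  expect_equal(d, qnorm(1 - 1 / 64) - qnorm(0.1))
  r2 <- rate_table(1, 0.1) # counts unknown
  expect_error(compute_dprime(r2, correct_extremes = TRUE), "count")
})

test_that("estimated sensitivity is unbiased at large trial counts", {
  sched <- generate_schedule(n_runs = 157, seed = 9) # ~1e4 trials
  dprime <- 1.5
  ests <- vapply(1:100, function(k) {
    resp <- generate_behavior(sched, dprime, 0.2, seed = 200 + k)
    compute_dprime(tabulate_rates(resp), correct_extremes = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(ests) - dprime), 0.02)
})
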