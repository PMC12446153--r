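test_that("EZ inverse-forward round trip is identity to 1e-8 on a grid", {
  grid <- expand.grid(v = c(-0.12, 0.1, 0.15, 0.2, 0.3),
                      a = c(0.08, 0.12, 0.16),
                      ter = c(0.2, 0.3))
  fw <- ez_forward(grid$v, grid$a, grid$ter)
  inv <- ez_inverse(fw$accuracy, fw$mean_rt, fw$var_rt)
  expect_lt(max(abs(inv$drift_v - grid$v)), 1e-8)
  expect_lt(max(abs(inv$boundary_a - grid$a)), 1e-8)
  expect_lt(max(abs(inv$ter - grid$ter)), 1e-8)
})

test_that("EZ inverse rejects degenerate accuracies; near-chance drift is near zero", {
  expect_error(ez_inverse(0.5, 0.5, 0.02), "drift undefined")
  expect_error(ez_inverse(1, 0.5, 0.02), "strictly inside")
  expect_error(ez_inverse(0, 0.5, 0.02), "strictly inside")
  expect_error(ez_inverse(0.9, 0.5, 0), "var_rt")
  # accuracy -> 0.5+ forces drift -> 0+
  v <- ez_inverse(c(0.5001, 0.50001), 0.5, 0.02)$drift_v
  expect_true(all(v > 0))
  expect_true(all(v < 0.01))
  expect_lt(v[2], v[1])
  # accuracy below one half gives negative drift with positive boundary
  inv <- ez_inverse(0.3, 0.45, 0.03)
  expect_lt(inv$drift_v, 0)
  expect_gt(inv$boundary_a, 0)
})

test_that("edge correction maps 0/1 accuracies half a trial inside", {
  expect_equal(edge_correct_accuracy(1, 100), 1 - 1 / 200)
  expect_equal(edge_correct_accuracy(0, 100), 1 / 200)
  expect_equal(edge_correct_accuracy(0.93, 100), 0.93)
  expect_equal(edge_correct_accuracy(c(1, 0.5, 0), 20),
               c(1 - 1 / 40, 0.5, 1 / 40))
})

test_that("forward predictions: additive ter, accuracy monotone in drift", {
  f1 <- ez_forward(0.2, 0.12, 0.25)
  f2 <- ez_forward(0.2, 0.12, 0.30)
  expect_equal(f2$mean_rt - f1$mean_rt, 0.05)
  expect_equal(f2$accuracy, f1$accuracy)
  expect_equal(f2$var_rt, f1$var_rt)
  acc <- ez_forward(c(0.05, 0.1, 0.2, 0.3), 0.12, 0.25)$accuracy
  expect_true(all(diff(acc) > 0))
  expect_error(ez_forward(0, 0.1, 0.2), "nonzero")
})

test_that("diffusion sampler moments match the EZ closed forms (3 MC SE at 1e5)", {
  sets <- list(c(0.2, 0.12, 0.25), c(0.1, 0.08, 0.3), c(-0.15, 0.1, 0.2),
               c(0.3, 0.16, 0.35), c(0.15, 0.14, 0.28))
  set.seed(424242)
  for (ps in sets) {
    tr <- sample_trials(ps[1], ps[2], ps[3], 1e5)
    fw <- ez_forward(ps[1], ps[2], ps[3])
    n <- nrow(tr)
    acc_se <- sqrt(fw$accuracy * (1 - fw$accuracy) / n)
    expect_lt(abs(mean(tr$correct) - fw$accuracy), 3 * acc_se)
    dt <- tr$rt[tr$correct == 1]
    m2 <- var(dt)
    m4 <- mean((dt - mean(dt))^4)
    expect_lt(abs(mean(dt) - fw$mean_rt), 3 * sd(dt) / sqrt(length(dt)))
    expect_lt(abs(m2 - fw$var_rt), 3 * sqrt((m4 - m2^2) / length(dt)))
  }
})

test_that("sampler basics: rt exceeds ter, zero drift is a fair coin, seeds reproduce", {
  tr <- sample_trials(0.25, 0.1, 0.3, 2000, seed = 11)
  expect_true(all(tr$rt > 0.3))
  expect_identical(tr, sample_trials(0.25, 0.1, 0.3, 2000, seed = 11))
  set.seed(12)
  tr0 <- sample_trials(0, 0.1, 0.2, 1e5)
  expect_lt(abs(mean(tr0$correct) - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_error(sample_trials(0.2, -0.1, 0.2, 10), "positive")
  expect_error(sample_trials(0.2, 0.1, -0.1, 10), "non-negative")
})

test_that("EZ inverse recovers the generating parameters from sampled moments", {
  set.seed(13)
  tr <- sample_trials(0.2, 0.12, 0.25, 1e5)
  dt <- tr$rt[tr$correct == 1]
  inv <- ez_inverse(mean(tr$correct), mean(dt), var(dt))
  # generous 3-SE-scale bands from the sampled-moment uncertainty
  expect_lt(abs(inv$drift_v - 0.2), 0.01)
  expect_lt(abs(inv$boundary_a - 0.12), 0.005)
  expect_lt(abs(inv$ter - 0.25), 0.01)
})

test_that("contaminant injection replaces an exact per-cell count from the uniform", {
  p <- cse_profile("flanker")
  d <- simulate_cse_dataset(p, 8, trials_per_cell = 100,
                            contaminant_rate = 0, seed = 21)
  expect_equal(sum(d$is_contaminant), 0L)
  set.seed(22)
  d5 <- inject_contaminants(d, rate = 0.05, lo = 0, hi = 3.09)
  cnt <- tapply(d5$is_contaminant,
                paste(d5$participant_id, d5$prev_congruency,
                      d5$congruency), sum)
  expect_true(all(cnt == 5L))
  expect_equal(nrow(d5), nrow(d))
  # non-contaminant rows unchanged
  keep <- d5$is_contaminant == 0L
  expect_equal(d5$rt[keep], d$rt[keep])
  expect_equal(d5$correct[keep], d$correct[keep])
  # identity at rate 0
  expect_identical(inject_contaminants(d, rate = 0), d)
  expect_error(inject_contaminants(d, rate = 0.05, lo = 2, hi = 1), "exceed")
})

test_that("contaminant RTs are Uniform(lo, hi): bounds and mean (3 MC SE)", {
  big <- toy_trials(rep(0.6, 4e5))
  set.seed(23)
  out <- inject_contaminants(big, rate = 1, lo = 0, hi = 3.09)
  expect_equal(sum(out$is_contaminant), 4e5)
  expect_lte(max(out$rt), 3.09)
  expect_gte(min(out$rt), 0)
  se <- (3.09 / sqrt(12)) / sqrt(4e5)
  expect_lt(abs(mean(out$rt) - 3.09 / 2), 3 * se)
  # correctness is a fair coin, independent of the process
  expect_lt(abs(mean(out$correct) - 0.5), 3 * sqrt(0.25 / 4e5))
})

test_that("simulated datasets have the contracted shape and reproduce under a seed", {
  p <- cse_profile("prime_probe")
  d <- simulate_cse_dataset(p, 6, trials_per_cell = 50, seed = 31)
  expect_equal(nrow(d), 6L * 4L * 50L)
  expect_true(all(d$rt > 0))
  expect_true(all(table(d$participant_id) == 200L))
  expect_identical(d, simulate_cse_dataset(p, 6, trials_per_cell = 50,
                                           seed = 31))
  d2 <- simulate_cse_dataset(p, 6, trials_per_cell = 50, seed = 32)
  expect_false(identical(d$rt, d2$rt))
})
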