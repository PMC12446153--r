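small_plan <- function(...) {
  multiverse_plan(effect_types = "flanker", sample_sizes = 12,
                  replicates = 2, trials_per_cell = 30,
                  filters = c("none", "sd2"), tests = "anova", seed = 99,
                  ...)
}

test_that("the same plan seed reproduces the multiverse bit-identically", {
  r1 <- run_multiverse(small_plan())
  r2 <- run_multiverse(small_plan())
  expect_identical(r1$cells, r2$cells)
  expect_identical(r1$runs$interaction_estimate, r2$runs$interaction_estimate)
  # a different master seed changes the data
  r3 <- run_multiverse(multiverse_plan(effect_types = "flanker",
                                       sample_sizes = 12, replicates = 2,
                                       trials_per_cell = 30,
                                       filters = c("none", "sd2"),
                                       tests = "anova", seed = 100))
  expect_false(identical(r1$runs$interaction_estimate,
                         r3$runs$interaction_estimate))
})

test_that("pathway cells respect the counting invariants", {
  r <- run_multiverse(small_plan())
  expect_equal(nrow(r$cells), 2L) # 2 filters x 1 test x 1 effect x 1 size
  expect_true(all(r$cells$n_decisions_1 <= r$cells$n_converged))
  expect_true(all(r$cells$n_converged <= r$cells$n_runs))
  expect_true(all(r$cells$n_runs == 2L))
  expect_false(any(r$cells$is_null))
})

test_that("rates pool by summing counts, never by averaging rates", {
  cells <- data.frame(effect_type = "x", is_null = TRUE,
                      n_participants = c(25, 50),
                      filter = "none", test = "anova",
                      n_runs = c(100, 100), n_converged = c(100, 100),
                      n_decisions_1 = c(10, 30))
  sm <- summarize_pathways(cells, aggregate_over = "n_participants")
  expect_equal(sm$rate, 40 / 200)
  expect_equal(sm$rate_type, "FPR")
  # simple tally: 3 of 4 converged decisions accepted
  one <- data.frame(effect_type = "x", is_null = FALSE, n_participants = 25,
                    filter = "none", test = "anova", n_runs = 4,
                    n_converged = 4, n_decisions_1 = 3)
  expect_equal(summarize_pathways(one)$rate, 0.75)
  # empty pooled cell: missing rate with warning
  zero <- one; zero$n_converged <- 0; zero$n_decisions_1 <- 0
  expect_warning(sz <- summarize_pathways(zero), "no converged")
  expect_true(is.na(sz$rate))
})

test_that("Wilson intervals match the closed form and an independent implementation", {
  ci <- wilson_ci(500, 1000)
  expect_equal(round(ci[, "low"], 3), c(low = 0.469))
  expect_equal(round(ci[, "high"], 3), c(high = 0.531))
  for (case in list(c(3, 10), c(26, 1000), c(0, 50), c(50, 50))) {
    ours <- wilson_ci(case[1], case[2])
    ref <- suppressWarnings(
      prop.test(case[1], case[2], correct = FALSE)$conf.int)
    expect_equal(unname(ours[, "low"]), ref[1], tolerance = 1e-9)
    expect_equal(unname(ours[, "high"]), ref[2], tolerance = 1e-9)
  }
  expect_true(is.na(wilson_ci(0, 0)[, "low"]))
})

test_that("interval bounds always bracket the rate inside [0, 1]", {
  x <- c(0, 1, 5, 99, 100)
  n <- rep(100, 5)
  ci <- wilson_ci(x, n)
  expect_true(all(ci[, "low"] >= 0 & ci[, "high"] <= 1))
  expect_true(all(ci[, "low"] <= x / n & x / n <= ci[, "high"]))
})

test_that("a non-converged run changes n_converged by one and never the decisions", {
  r <- run_multiverse(small_plan())
  runs <- r$runs
  fake <- runs[1, ]
  fake$converged <- FALSE
  fake$decision <- 0L
  fake$replicate <- 3L
  with_fake <- csemultiverse:::.tally_cells(rbind(runs, fake))
  without <- csemultiverse:::.tally_cells(runs)
  i <- with_fake$filter == fake$filter & with_fake$test == fake$test
  j <- without$filter == fake$filter & without$test == fake$test
  expect_equal(with_fake$n_runs[i], without$n_runs[j] + 1L)
  expect_equal(with_fake$n_converged[i], without$n_converged[j])
  expect_equal(with_fake$n_decisions_1[i], without$n_decisions_1[j])
})

test_that("summary and print methods work on a mixed true/null run", {
  plan <- multiverse_plan(effect_types = c("flanker", "flanker_null"),
                          sample_sizes = 12, replicates = 2,
                          trials_per_cell = 30, filters = "none",
                          tests = "anova", seed = 5)
  r <- run_multiverse(plan)
  sm <- summary(r)
  expect_setequal(sm$rate_type, c("TPR", "FPR"))
  expect_true(all(sm$ci_low <= sm$rate & sm$rate <= sm$ci_high,
                  na.rm = TRUE))
  expect_output(print(r), "CSE multiverse run")
})
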