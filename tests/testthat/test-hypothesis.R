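test_that("error-trial exclusion keeps exactly the correct trials", {
  p <- cse_profile("flanker")
  d <- simulate_cse_dataset(p, 6, seed = 61)
  ex <- exclude_errors(d)
  expect_equal(nrow(ex), sum(d$correct == 1L))
  expect_true(all(ex$correct == 1L))
  all_ok <- d; all_ok$correct <- 1L
  expect_equal(nrow(exclude_errors(all_ok)), nrow(d))
})

test_that("pathway results are invariant to error-trial RT values", {
  p <- cse_profile("prime_probe")
  d <- simulate_cse_dataset(p, 12, seed = 62)
  pert <- d
  pert$rt[pert$correct == 0L] <- pert$rt[pert$correct == 0L] * 10 + 1
  r1 <- run_pathways(d, filters = c("none", "sd2"), tests = "anova")
  r2 <- run_pathways(pert, filters = c("none", "sd2"), tests = "anova")
  expect_equal(r1$interaction_estimate, r2$interaction_estimate)
  expect_equal(r1$interaction_p, r2$interaction_p)
})

test_that("rm-ANOVA interaction is the squared paired t on CSE scores", {
  p <- cse_profile("prime_probe")
  d <- exclude_errors(simulate_cse_dataset(p, 25, seed = 63))
  res <- rm_anova_cse(d)
  means <- tapply(d$rt, list(d$participant_id,
                             paste0(d$prev_congruency, d$congruency)), mean)
  scores <- (means[, "cI"] - means[, "cC"]) - (means[, "iI"] - means[, "iC"])
  tt <- t.test(scores)
  expect_equal(res$interaction_p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$interaction_estimate, -mean(scores) * 1000,
               tolerance = 1e-8)
  # F equals t^2 (recovered from the p-value via the F quantile)
  f_from_p <- qf(res$interaction_p, 1, nrow(means) - 1, lower.tail = FALSE)
  expect_equal(f_from_p, unname(tt$statistic)^2, tolerance = 1e-6)
})

test_that("rm-ANOVA agrees with aov()'s within-participant error stratum", {
  d <- exclude_errors(simulate_cse_dataset(cse_profile("flanker"), 12,
                                           seed = 631))
  res <- rm_anova_cse(d)
  means <- tapply(d$rt, list(d$participant_id,
                             paste0(d$prev_congruency, d$congruency)), mean)
  n <- nrow(means)
  long <- data.frame(
    pp = factor(rep(rownames(means), 4L)),
    prev = factor(rep(c("c", "c", "i", "i"), each = n)),
    cur = factor(rep(c("C", "I", "C", "I"), each = n)),
    mrt = c(means[, "cC"], means[, "cI"], means[, "iC"], means[, "iI"]))
  sm <- summary(stats::aov(mrt ~ prev * cur + Error(pp / (prev * cur)),
                           data = long))
  ref <- sm[["Error: pp:prev:cur"]][[1L]]["prev:cur", "Pr(>F)"]
  expect_equal(res$interaction_p, ref, tolerance = 1e-10)
})

test_that("rm-ANOVA handles flat data, directionality and incomplete participants", {
  flat <- toy_dataset(list(cC = rep(0.5, 5), cI = rep(0.5, 5),
                           iC = rep(0.5, 5), iI = rep(0.5, 5)), n_pp = 4L)
  flat$rt <- flat$rt + rep(c(0, 0.01, 0.02, 0.03), each = 20) # pp shifts only
  res <- rm_anova_cse(flat)
  expect_equal(res$decision, 0L)
  # reversed (positive) interaction: significant but wrong direction
  set.seed(640)
  pos <- toy_dataset(list(cC = rep(0.50, 8), cI = rep(0.52, 8),
                          iC = rep(0.50, 8), iI = rep(0.60, 8)), n_pp = 6L)
  pos$rt <- pos$rt + rnorm(nrow(pos), 0, 1e-4)
  rpos <- rm_anova_cse(pos)
  expect_lt(rpos$interaction_p, 0.05)
  expect_gt(rpos$interaction_estimate, 0)
  expect_equal(rpos$decision, 0L)
  # a participant missing one cell is dropped
  d <- exclude_errors(simulate_cse_dataset(cse_profile("flanker"), 6,
                                           seed = 64))
  d <- d[!(d$participant_id == 3 & d$prev_congruency == "i" &
           d$congruency == "I"), ]
  rd <- rm_anova_cse(d)
  expect_equal(rd$n_participants, 5L)
  expect_match(paste(rd$notes, collapse = " "), "dropped")
})

test_that("LMM fits satisfy the nested-model identities", {
  p <- cse_profile("prime_probe")
  d <- exclude_errors(simulate_cse_dataset(p, 20, seed = 65))
  res <- fit_lmm_cse(d, "lmm")
  expect_true(res$converged)
  # LRT statistic recovered from its p must be non-negative and match dAIC + 2
  lrt_stat <- qchisq(res$lrt_p, 1, lower.tail = FALSE)
  expect_gte(lrt_stat, 0)
  expect_equal(res$delta_aic, lrt_stat - 2, tolerance = 1e-6)
  # BIC penalty for one parameter: dBIC = LRT - log(n)
  expect_equal(res$delta_bic, lrt_stat - log(res$n_trials_analyzed),
               tolerance = 1e-6)
})

test_that("log-variant fits on exponentiated data reproduce raw-variant estimates", {
  set.seed(66)
  pp <- rep(1:10, each = 80)
  cur <- rep(rep(c(0, 1), each = 40), 10)
  prev <- rep(rep(c(0, 1, 0, 1), each = 20), 10)
  y <- 0.6 + 0.05 * cur + 0.01 * prev - 0.03 * cur * prev +
    rep(rnorm(10, 0, 0.05), each = 80) + rnorm(800, 0, 0.1)
  base <- data.frame(participant_id = pp,
                     prev_congruency = factor(ifelse(prev == 1, "i", "c"),
                                              levels = c("c", "i")),
                     congruency = factor(ifelse(cur == 1, "I", "C"),
                                         levels = c("C", "I")),
                     rt = y, correct = 1L, is_contaminant = 0L,
                     trial_index = 1L)
  expd <- base
  expd$rt <- exp(base$rt)
  raw <- fit_lmm_cse(base, "lmm")
  logv <- fit_lmm_cse(expd, "loglmm")
  expect_equal(logv$interaction_estimate, raw$interaction_estimate / 1000,
               tolerance = 1e-5)
  expect_equal(logv$lrt_p, raw$lrt_p, tolerance = 1e-6)
})

test_that("complex LMM recovers the generating interaction on stage-1 data", {
  p <- cse_profile("prime_probe")
  eff <- sample_participants(p, 120, seed = 67)
  cells <- simulate_stage1(p, eff, 100, seed = 68, keep_trials = TRUE)
  res <- fit_lmm_cse(attr(cells, "trials"), "lmm_cx")
  expect_true(res$converged)
  se_ms <- 2 * p$resid_sd / sqrt(120 * 100)
  expect_lt(abs(res$interaction_estimate - p$beta_interaction), 3 * se_ms)
})

test_that("the composite decision rule enforces all four criteria", {
  mk <- function(daic, dbic, lrt_p, wald_p, est)
    csemultiverse:::.test_result("lmm_simple", TRUE,
                                 interaction_estimate = est,
                                 interaction_p = wald_p, lrt_p = lrt_p,
                                 delta_aic = daic, delta_bic = dbic)
  # information criteria below both thresholds: reject
  expect_equal(decide(mk(1.5, 3, 0.01, 0.01, -10)), 0L)
  # wrong direction despite everything else: reject
  expect_equal(decide(mk(5, 8, 0.01, 0.01, +8)), 0L)
  # all four satisfied: accept
  expect_equal(decide(mk(5, 8, 0.01, 0.01, -8)), 1L)
  # BIC route alone suffices for the information criterion
  expect_equal(decide(mk(1, 6.5, 0.01, 0.01, -8)), 1L)
  # non-significant LRT or Wald: reject
  expect_equal(decide(mk(5, 8, 0.2, 0.01, -8)), 0L)
  expect_equal(decide(mk(5, 8, 0.01, 0.2, -8)), 0L)
  nc <- csemultiverse:::.test_result("lmm_simple", FALSE)
  expect_error(decide(nc), "non-converged")
})

test_that("convergence failures are recorded, never thrown", {
  # two trials per participant cannot identify a random slope + residual:
  # the fit is singular or warns, and must come back converged = FALSE
  tiny <- toy_dataset(list(cC = 0.5, cI = 0.55, iC = 0.52, iI = 0.58),
                      n_pp = 3L)
  expect_silent(res <- fit_lmm_cse(tiny, "lmm_cx"))
  expect_false(res$converged)
  expect_equal(res$decision, 0L)
})
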