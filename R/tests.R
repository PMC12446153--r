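#' Exclude error trials
#'
#' Standard first preprocessing step on every pathway: only correct trials
#' are analysed. Cells that lose all their trials are flagged in attribute
#' `"dropped_cells"`.
#'
#' @param trials a trial table with a `correct` column.
#' @return the correct-trial rows.
#' @export
exclude_errors <- function(trials) {
  ok <- trials$correct == 1L
  out <- trials[ok, , drop = FALSE]
  cid <- .cell_id(trials)
  n_in <- tabulate(cid$id, cid$n)
  n_kept <- tabulate(cid$id[ok], cid$n)
  dropped <- n_in > 0L & n_kept == 0L
  lay <- c("cC", "cI", "iC", "iI")
  attr(out, "dropped_cells") <-
    paste(rep(cid$participants, each = 4L), lay, sep = ".")[dropped]
  out
}

# Common TestResult container.
.test_result <- function(kind, converged, interaction_estimate = NA_real_,
                         interaction_p = NA_real_, lrt_p = NA_real_,
                         delta_aic = NA_real_, delta_bic = NA_real_,
                         decision = 0L, n_participants = NA_integer_,
                         n_trials_analyzed = NA_integer_,
                         notes = character(0)) {
  structure(list(kind = kind, converged = converged,
                 interaction_estimate = interaction_estimate,
                 interaction_p = interaction_p, lrt_p = lrt_p,
                 delta_aic = delta_aic, delta_bic = delta_bic,
                 decision = decision, n_participants = n_participants,
                 n_trials_analyzed = n_trials_analyzed, notes = notes),
            class = "cse_test")
}

#' @export
print.cse_test <- function(x, ...) {
  cat("CSE hypothesis test [", x$kind, "] ", sep = "")
  if (!x$converged) {
    cat("-- did not converge\n")
    if (length(x$notes)) cat("  ", paste(x$notes, collapse = "; "), "\n")
    return(invisible(x))
  }
  cat(sprintf("\n  interaction estimate %.3f (%s), p = %.4g\n",
              x$interaction_estimate,
              if (grepl("log", x$kind)) "log-units" else "ms",
              x$interaction_p))
  if (!is.na(x$lrt_p))
    cat(sprintf("  LRT p = %.4g, dAIC = %.2f, dBIC = %.2f\n",
                x$lrt_p, x$delta_aic, x$delta_bic))
  cat("  decision:", x$decision,
      sprintf("(n = %d participants, %d trials)\n", x$n_participants,
              x$n_trials_analyzed))
  invisible(x)
}

#' 2x2 repeated-measures ANOVA test for the CSE
#'
#' Aggregates RTs to per-participant condition means and tests the
#' previous-by-current congruency interaction with a repeated-measures
#' ANOVA (`aov` with a within-participant error stratum; F on 1 and n-1
#' df). The interaction estimate is the mean over participants of
#' `(iI - iC) - (cI - cC)` in ms (the dummy-coded interaction coefficient;
#' negative for a CSE). The alternative is accepted iff the interaction is
#' significant at alpha = .05 *and* the estimate is negative. Participants
#' missing any of the four cells are dropped (noted in `notes`).
#'
#' @param trials a trial table (error trials already excluded upstream).
#' @param alpha significance level (default .05).
#' @return a `cse_test` result.
#' @export
rm_anova_cse <- function(trials, alpha = 0.05) {
  cid <- .cell_id(trials)
  cnt <- tabulate(cid$id, cid$n)
  tot <- numeric(cid$n)
  rs <- rowsum(trials$rt, cid$id)
  tot[as.integer(rownames(rs))] <- rs
  means <- matrix(ifelse(cnt > 0, tot / cnt, NA_real_),
                  ncol = 4L, byrow = TRUE,
                  dimnames = list(cid$participants,
                                  c("cC", "cI", "iC", "iI")))
  complete <- stats::complete.cases(means)
  notes <- character(0)
  if (any(!complete))
    notes <- paste(sum(!complete), "participant(s) dropped: missing cells")
  means <- means[complete, , drop = FALSE]
  n <- nrow(means)
  if (n < 2L)
    return(.test_result("rm_anova", FALSE,
                        notes = c(notes, "fewer than 2 complete participants")))
  # classical 2x2 within-subject decomposition: each 1-df effect is tested
  # against its own effect-by-participant stratum (O(n); equivalent to
  # aov() with Error(pp/(prev*cur)), cross-checked in the test suite)
  d_int <- (means[, "iI"] - means[, "iC"]) -
    (means[, "cI"] - means[, "cC"])
  f_int <- n * mean(d_int)^2 / stats::var(d_int)
  p_int <- stats::pf(f_int, 1, n - 1, lower.tail = FALSE)
  est_ms <- mean(d_int) * 1000
  res <- .test_result("rm_anova", TRUE,
                      interaction_estimate = est_ms,
                      interaction_p = p_int,
                      n_participants = n,
                      n_trials_analyzed = nrow(trials),
                      notes = notes)
  res$decision <- decide(res, alpha = alpha)
  res
}

# Evaluate an expression while recording every warning and message (lme4
# reports trouble through both channels).
.fit_quietly <- function(expr) {
  warns <- character(0)
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(expr, error = function(e) e),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  list(fit = fit, warnings = warns, messages = msgs)
}

.lmm_ok <- function(q) {
  if (inherits(q$fit, "error")) return(FALSE)
  if (length(q$warnings) || length(q$messages)) return(FALSE)
  if (lme4::isSingular(q$fit, tol = 1e-4)) return(FALSE)
  conv <- q$fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) return(FALSE)
  TRUE
}

#' Mixed-effects likelihood-ratio test for the CSE
#'
#' Fits the alternative and null mixed models by maximum likelihood with
#' `lme4::lmer` and compares them with a likelihood-ratio test. The
#' alternative model is `y ~ congruency * previous + (1 | participant)`
#' (simple kinds) or `(1 + congruency | participant)` (complex kinds), with
#' `y` the raw RT in seconds or `log(RT)` for the log kinds; the null model
#' drops only the interaction term. Recorded diagnostics: the Wald z p of
#' the interaction coefficient, the LRT p (chi-squared, 1 df), and
#' `AIC(null) - AIC(alt)` / `BIC(null) - BIC(alt)`. Any optimizer failure,
#' singular fit or emitted warning/message in either fit marks the result
#' as non-converged (the engine excludes such runs from rate summaries);
#' no condition propagates.
#'
#' @param trials a trial table (error trials already excluded upstream).
#' @param spec a test code other than `"anova"` (see [test_spec()]).
#' @param alpha significance level (default .05).
#' @return a `cse_test` result.
#' @export
fit_lmm_cse <- function(trials, spec, alpha = 0.05) {
  spec <- test_spec(spec)
  if (spec$kind == "rm_anova")
    stop("use rm_anova_cse() for the ANOVA pathway", call. = FALSE)
  if (nrow(trials) == 0L) stop("trials table is empty", call. = FALSE)
  dat <- data.frame(
    y = if (spec$log) log(trials$rt) else trials$rt,
    cur = as.numeric(trials$congruency == "I"),
    prev = as.numeric(trials$prev_congruency == "i"),
    pp = factor(trials$participant_id)
  )
  re <- if (spec$slope) "(1 + cur | pp)" else "(1 | pp)"
  f_alt <- stats::as.formula(paste("y ~ cur * prev +", re))
  f_null <- stats::as.formula(paste("y ~ cur + prev +", re))
  q_alt <- .fit_quietly(lme4::lmer(f_alt, data = dat, REML = FALSE))
  q_null <- .fit_quietly(lme4::lmer(f_null, data = dat, REML = FALSE))
  if (!.lmm_ok(q_alt) || !.lmm_ok(q_null)) {
    notes <- unique(c(
      if (inherits(q_alt$fit, "error")) conditionMessage(q_alt$fit),
      if (inherits(q_null$fit, "error")) conditionMessage(q_null$fit),
      q_alt$warnings, q_alt$messages, q_null$warnings, q_null$messages))
    return(.test_result(spec$kind, FALSE,
                        n_participants = nlevels(dat$pp),
                        n_trials_analyzed = nrow(dat),
                        notes = notes))
  }
  alt <- q_alt$fit
  null <- q_null$fit
  co <- lme4::fixef(alt)["cur:prev"]
  se <- sqrt(diag(as.matrix(stats::vcov(alt)))[["cur:prev"]])
  wald_p <- 2 * stats::pnorm(-abs(co / se))
  lrt <- 2 * (as.numeric(stats::logLik(alt)) -
              as.numeric(stats::logLik(null)))
  lrt_p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  res <- .test_result(
    spec$kind, TRUE,
    interaction_estimate = if (spec$log) unname(co) else unname(co) * 1000,
    interaction_p = wald_p,
    lrt_p = lrt_p,
    delta_aic = stats::AIC(null) - stats::AIC(alt),
    delta_bic = stats::BIC(null) - stats::BIC(alt),
    n_participants = nlevels(dat$pp),
    n_trials_analyzed = nrow(dat))
  res$decision <- decide(res, alpha = alpha)
  res
}

#' Composite decision rule for accepting the CSE alternative
#'
#' For mixed-model results the alternative is accepted (1) iff all of:
#' `delta_aic >= 2` *or* `delta_bic >= 6`; LRT p below alpha; interaction
#' coefficient significant (Wald) below alpha; and the interaction estimate
#' negative (the hypothesised direction). For the ANOVA, significance plus
#' direction. Requires a converged result.
#'
#' @param result a converged `cse_test`.
#' @param alpha significance level (default .05).
#' @return integer 0 or 1.
#' @export
decide <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "cse_test"))
  if (!isTRUE(result$converged))
    stop("decision undefined for a non-converged result; exclude the run",
         call. = FALSE)
  # isTRUE() also maps undefined statistics (e.g. a 0/0 F) to "no evidence"
  if (result$kind == "rm_anova") {
    return(as.integer(isTRUE(result$interaction_p < alpha) &&
                      isTRUE(result$interaction_estimate < 0)))
  }
  as.integer((isTRUE(result$delta_aic >= 2) ||
              isTRUE(result$delta_bic >= 6)) &&
             isTRUE(result$lrt_p < alpha) &&
             isTRUE(result$interaction_p < alpha) &&
             isTRUE(result$interaction_estimate < 0))
}

#' Run every decision pathway on one dataset
#'
#' Excludes error trials once, then applies each outlier filter and runs
#' each hypothesis test on the filtered data, mirroring one dataset's walk
#' through the full decision tree.
#'
#' @param trials a trial table from [simulate_cse_dataset()] (or a
#'   user-supplied table with the same columns).
#' @param filters,tests character vectors of codes.
#' @param alpha significance level.
#' @return data.frame with one row per pathway: `filter`, `test`,
#'   `converged`, `decision`, `interaction_estimate`, `interaction_p`,
#'   `lrt_p`, `delta_aic`, `delta_bic`, `n_participants`,
#'   `n_trials_analyzed`.
#' @export
run_pathways <- function(trials, filters = default_filter_codes(),
                         tests = default_test_codes(), alpha = 0.05) {
  correct_only <- exclude_errors(trials)
  rows <- vector("list", length(filters) * length(tests))
  i <- 0L
  for (f in filters) {
    filtered <- apply_filter(correct_only, f)
    for (tst in tests) {
      res <- if (test_spec(tst)$kind == "rm_anova")
        rm_anova_cse(filtered, alpha = alpha)
      else
        fit_lmm_cse(filtered, tst, alpha = alpha)
      i <- i + 1L
      rows[[i]] <- data.frame(
        filter = f, test = tst,
        converged = res$converged,
        decision = res$decision,
        interaction_estimate = res$interaction_estimate,
        interaction_p = res$interaction_p,
        lrt_p = res$lrt_p,
        delta_aic = res$delta_aic,
        delta_bic = res$delta_bic,
        n_participants = res$n_participants,
        n_trials_analyzed = res$n_trials_analyzed)
    }
  }
  do.call(rbind, rows)
}
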