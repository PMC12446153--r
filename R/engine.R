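#' Run a multiverse simulation
#'
#' Generates every dataset of the plan (effect types x sample sizes x
#' replicates), pushes each through every decision pathway (filters x
#' tests), and tallies decisions per pathway cell. Each dataset's sub-seed
#' is a deterministic function of the master seed and its grid coordinates
#' ([dataset_seed()]), so all pathways analyse bit-identical data and two
#' runs of the same plan agree exactly. Non-converged fits are recorded and
#' later excluded from rate summaries (never counted as decision 0).
#'
#' @param plan a [multiverse_plan()].
#' @param keep_runs keep the per-run result table (default `TRUE`).
#' @param progress print a line per plan cell (default `FALSE`).
#' @return an object of class `cse_multiverse` with elements `plan`,
#'   `cells` (per pathway-cell counts: `effect_type`, `is_null`,
#'   `n_participants`, `filter`, `test`, `n_runs`, `n_converged`,
#'   `n_decisions_1`) and `runs` (per-run diagnostics, if kept).
#' @seealso [summarize_pathways()], [summary.cse_multiverse()],
#'   [plot.cse_multiverse()]
#' @export
run_multiverse <- function(plan, keep_runs = TRUE, progress = FALSE) {
  stopifnot(inherits(plan, "multiverse_plan"))
  run_list <- list()
  k <- 0L
  for (ei in seq_along(plan$effect_types)) {
    params <- plan$profiles[[ei]]
    for (si in seq_along(plan$sample_sizes)) {
      n <- plan$sample_sizes[si]
      if (progress)
        cat("effect", params$label, "n =", n, ":", plan$replicates,
            "replicates\n")
      for (r in seq_len(plan$replicates)) {
        sd_r <- dataset_seed(plan$seed, ei, si, r)
        trials <- simulate_cse_dataset(
          params, n, plan$trials_per_cell,
          contaminant_rate = plan$contaminant_rate,
          contaminant_lo = plan$contaminant_lo,
          contaminant_hi = plan$contaminant_hi,
          s = plan$scaling_s, seed = sd_r)
        res <- run_pathways(trials, plan$filters, plan$tests)
        res$effect_type <- params$label
        res$is_null <- params$beta_interaction == 0
        res$n_participants <- n
        res$replicate <- r
        res$dataset_seed <- sd_r
        k <- k + 1L
        run_list[[k]] <- res
      }
    }
  }
  runs <- do.call(rbind, run_list)
  cells <- .tally_cells(runs)
  structure(list(plan = plan, cells = cells,
                 runs = if (keep_runs) runs else NULL),
            class = "cse_multiverse")
}

# Aggregate per-run decisions into pathway-cell counts.
.tally_cells <- function(runs) {
  key <- interaction(runs$effect_type, runs$n_participants, runs$filter,
                     runs$test, drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  cells <- data.frame(
    effect_type = runs$effect_type[first],
    is_null = runs$is_null[first],
    n_participants = runs$n_participants[first],
    filter = runs$filter[first],
    test = runs$test[first],
    n_runs = as.vector(tapply(rep(1L, nrow(runs)), key, sum)[key[first]]),
    n_converged = as.vector(tapply(runs$converged, key, sum)[key[first]]),
    n_decisions_1 = as.vector(
      tapply(runs$decision[runs$converged],
             key[runs$converged], sum)[as.character(key[first])])
  )
  cells$n_decisions_1[is.na(cells$n_decisions_1)] <- 0L
  rownames(cells) <- NULL
  cells
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return matrix with columns `low` and `high` (NA when `n = 0`).
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- ifelse(n > 0, x / n, NA_real_)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  out <- cbind(low = centre - half, high = centre + half)
  out[n == 0, ] <- NA_real_
  out
}

#' Pool pathway cells and compute rates with intervals
#'
#' Pools decision counts over the requested fields by *summing counts*
#' (never averaging rates), then computes `rate = n_decisions_1 /
#' n_converged` with a Wilson interval on the pooled counts. The rate is a
#' true-positive rate on true-effect types and a false-positive rate on
#' null types (`rate_type` column). Pooled cells with no converged runs
#' yield a missing rate with a warning.
#'
#' @param cells the `cells` table of a `cse_multiverse` (or compatible
#'   counts table).
#' @param aggregate_over character vector of fields to pool over, any of
#'   `"effect_type"`, `"n_participants"`, `"filter"`, `"test"`.
#' @param conf confidence level for the Wilson interval.
#' @param ci interval method: `"wilson"` (default) or `"normal"`
#'   (Wald approximation).
#' @return data.frame of pooled counts, `rate`, `ci_low`, `ci_high`,
#'   `rate_type`.
#' @export
summarize_pathways <- function(cells, aggregate_over = character(0),
                               conf = 0.95, ci = c("wilson", "normal")) {
  ci <- match.arg(ci)
  if (nrow(cells) == 0L) stop("no pathway cells to summarize", call. = FALSE)
  fields <- c("effect_type", "n_participants", "filter", "test")
  bad <- setdiff(aggregate_over, fields)
  if (length(bad))
    stop("unknown field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  keep <- setdiff(fields, aggregate_over)
  if (length(keep)) {
    key <- interaction(cells[keep], drop = TRUE, lex.order = TRUE)
  } else {
    key <- factor(rep("all", nrow(cells)))
  }
  first <- !duplicated(key)
  out <- cells[first, keep, drop = FALSE]
  out$n_runs <- as.vector(tapply(cells$n_runs, key, sum)[key[first]])
  out$n_converged <- as.vector(tapply(cells$n_converged, key,
                                      sum)[key[first]])
  out$n_decisions_1 <- as.vector(tapply(cells$n_decisions_1, key,
                                        sum)[key[first]])
  out$rate_type <- as.vector(tapply(cells$is_null, key, function(z) {
    if (all(z)) "FPR" else if (all(!z)) "TPR" else "mixed"
  })[key[first]])
  out$rate <- ifelse(out$n_converged > 0,
                     out$n_decisions_1 / out$n_converged, NA_real_)
  if (any(out$n_converged == 0))
    warning("pooled cell(s) with no converged runs: rate undefined",
            call. = FALSE)
  if (ci == "wilson") {
    iv <- wilson_ci(out$n_decisions_1, out$n_converged, conf)
  } else {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    se <- sqrt(out$rate * (1 - out$rate) / out$n_converged)
    iv <- cbind(low = pmax(out$rate - z * se, 0),
                high = pmin(out$rate + z * se, 1))
    iv[out$n_converged == 0, ] <- NA_real_
  }
  out$ci_low <- iv[, "low"]
  out$ci_high <- iv[, "high"]
  rownames(out) <- NULL
  out
}

#' @export
print.cse_multiverse <- function(x, ...) {
  cts <- plan_counts(x$plan)
  tot_runs <- sum(x$cells$n_runs)
  tot_conv <- sum(x$cells$n_converged)
  cat("CSE multiverse run\n")
  cat(sprintf("  %d pathway(s) x %d dataset(s) = %d analyses; %.1f%% converged\n",
              cts$n_pathways, cts$n_datasets, tot_runs,
              100 * tot_conv / max(tot_runs, 1)))
  sm <- summary(x, by = c("filter", "test"))
  for (kind in intersect(c("TPR", "FPR"), sm$rate_type)) {
    part <- sm[sm$rate_type == kind, ]
    cat("  pooled ", kind,
        " per pathway (over effect types and sample sizes):\n", sep = "")
    print(utils::head(part[order(-part$rate),
                           c("filter", "test", "n_converged", "rate",
                             "ci_low", "ci_high")], 6),
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Summarize a multiverse run
#'
#' @param object a `cse_multiverse`.
#' @param by fields to keep disaggregated (default `filter` and `test`);
#'   everything else is pooled by counts. Effect types are always split
#'   into true-effect and null groups so that TPR and FPR are never mixed.
#' @param conf confidence level.
#' @param ... unused.
#' @return a [summarize_pathways()] table computed separately on
#'   true-effect and null cells and row-bound.
#' @export
summary.cse_multiverse <- function(object, by = c("filter", "test"),
                                   conf = 0.95, ...) {
  fields <- c("effect_type", "n_participants", "filter", "test")
  agg <- setdiff(fields, by)
  parts <- lapply(split(object$cells, object$cells$is_null),
                  summarize_pathways, aggregate_over = agg, conf = conf)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Plot pooled TPR against FPR per pathway
#'
#' Scatter of the pooled true-positive rate (true-effect datasets) against
#' the pooled false-positive rate (null datasets) for every filter-by-test
#' pathway, with the nominal 0.025 directional alpha marked. Requires both
#' true-effect and null effect types in the run.
#'
#' @param x a `cse_multiverse`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cse_multiverse <- function(x, ...) {
  sm <- summary(x, by = c("filter", "test"))
  tpr <- sm[sm$rate_type == "TPR", ]
  fpr <- sm[sm$rate_type == "FPR", ]
  if (!nrow(tpr) || !nrow(fpr))
    stop("plot needs both true-effect and null effect types", call. = FALSE)
  key <- paste(tpr$filter, tpr$test)
  m <- match(key, paste(fpr$filter, fpr$test))
  tests <- factor(tpr$test)
  graphics::plot(fpr$rate[m], tpr$rate, xlab = "False positive rate",
                 ylab = "True positive rate", pch = 19,
                 col = as.integer(tests), xlim = c(0, max(fpr$rate) * 1.2),
                 ylim = c(0, 1), ...)
  graphics::abline(v = 0.025, lty = 2, col = "grey40")
  graphics::legend("bottomright", legend = levels(tests), pch = 19,
                   col = seq_len(nlevels(tests)), bty = "n", cex = 0.8)
  invisible(x)
}
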