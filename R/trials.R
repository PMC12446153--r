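#' Sample trials from a simple diffusion process
#'
#' Draws first-passage samples of a Wiener process with drift `drift_v`,
#' absorbing boundaries at 0 and `boundary_a`, unbiased start
#' `boundary_a/2` and diffusion coefficient `s`. Crossing the upper
#' boundary is a correct response; `ter` is added to every passage time.
#' Sampling inverts the exact series CDF of the decision time (compiled
#' code), so the draws follow the first-passage distribution without
#' discretisation bias; see `ez_forward()` for the matching closed-form
#' moments.
#'
#' @param drift_v drift rate.
#' @param boundary_a boundary separation (> 0).
#' @param ter non-decision time in seconds (>= 0).
#' @param n number of trials (>= 1).
#' @param s diffusion scaling constant (default 0.1).
#' @param seed optional integer seed.
#' @return data.frame with columns `rt` (seconds) and `correct` (0/1).
#' @export
sample_trials <- function(drift_v, boundary_a, ter, n, s = 0.1,
                          seed = NULL) {
  stopifnot(length(drift_v) == 1L, length(boundary_a) == 1L,
            length(ter) == 1L)
  if (boundary_a <= 0) stop("boundary_a must be positive", call. = FALSE)
  if (ter < 0) stop("ter must be non-negative", call. = FALSE)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  smp <- .fpt_sample_cells(as.integer(n), drift_v, boundary_a, s)
  data.frame(rt = smp$rt + ter, correct = smp$upper)
}

#' Replace a fixed share of trials with uniform contaminants
#'
#' Models inattention: in every participant-by-condition cell, exactly
#' `round(rate * n_cell)` trials are replaced by RTs drawn from
#' Uniform(`lo`, `hi`) seconds, with correctness resampled as a fair coin
#' (contaminants do not depend on the decision process). All other rows are
#' untouched and row count and order are preserved.
#'
#' @param trials a trial table (see [simulate_cse_dataset()]).
#' @param rate proportion of trials per cell to replace, in `[0, 1]`.
#' @param lo,hi contaminant RT bounds in seconds, `lo < hi`.
#' @param seed optional integer seed.
#' @return the trial table with contaminated rows flagged
#'   (`is_contaminant = 1`).
#' @export
inject_contaminants <- function(trials, rate = 0.05, lo = 0, hi = 3.09,
                                seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  if (hi <= lo) stop("hi must exceed lo", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(trials)
  idx <- split(seq_len(nrow(trials)), .cell_id(trials)$id)
  picked <- unlist(lapply(idx, function(i) {
    m <- round(rate * length(i))
    if (m == 0) integer(0) else i[sample.int(length(i), m)]
  }), use.names = FALSE)
  if (length(picked)) {
    trials$rt[picked] <- stats::runif(length(picked), lo, hi)
    trials$correct[picked] <- stats::rbinom(length(picked), 1L, 0.5)
    trials$is_contaminant[picked] <- 1L
  }
  trials
}

#' Simulate one complete CSE dataset
#'
#' Runs the full two-stage generative pipeline for a single dataset:
#'
#' 1. participant random effects ([sample_participants()]);
#' 2. Gaussian stage-1 trials aggregated to cell summaries
#'    ([simulate_stage1()]);
#' 3. edge-corrected accuracies and the EZ transformation to per-cell
#'    diffusion parameters ([ez_inverse()]);
#' 4. trial-level RT/accuracy resampling from the diffusion process
#'    (`trials_per_cell` per cell);
#' 5. uniform contaminant injection ([inject_contaminants()]).
#'
#' A cell whose edge-corrected accuracy lands exactly on 0.5 leaves the
#' drift undefined; the whole replicate is then regenerated from a shifted
#' sub-seed (recorded in attribute `"attempts"`). Negative non-decision
#' times (possible in very noisy cells) are floored at zero; the count is
#' recorded in attribute `"n_ter_floored"`.
#'
#' @param params a `cse_params` profile.
#' @param n_participants number of participants.
#' @param trials_per_cell trials per condition per participant.
#' @param contaminant_rate,contaminant_lo,contaminant_hi contaminant
#'   settings (proportion; bounds in seconds).
#' @param s diffusion scaling constant.
#' @param seed optional integer seed (sub-seeds for regeneration are
#'   derived from it).
#' @param max_attempts regeneration cap for degenerate replicates.
#' @return trial table: `participant_id`, `prev_congruency` (`c`/`i`),
#'   `congruency` (`C`/`I`), `rt` (seconds), `correct`, `is_contaminant`,
#'   `trial_index`; `4 * trials_per_cell` rows per participant. Attributes:
#'   `effect_label`, `seed`, `attempts`, `n_ter_floored`.
#' @export
simulate_cse_dataset <- function(params, n_participants,
                                 trials_per_cell = 100,
                                 contaminant_rate = 0.05,
                                 contaminant_lo = 0, contaminant_hi = 3.09,
                                 s = 0.1, seed = NULL, max_attempts = 25L) {
  validate_cse_params(params)
  for (attempt in seq_len(max_attempts)) {
    if (!is.null(seed)) set.seed(seed + (attempt - 1L) * 1000003)
    eff <- sample_participants(params, n_participants)
    cells <- simulate_stage1(params, eff, trials_per_cell)
    acc <- edge_correct_accuracy(cells$accuracy, cells$n_trials)
    if (any(acc == 0.5)) next # undefined drift: regenerate the replicate
    dp <- ez_inverse(acc, cells$mean_rt, cells$var_rt, s = s)
    n_floored <- sum(dp$ter < 0)
    dp$ter <- pmax(dp$ter, 0)
    smp <- .fpt_sample_cells(rep(as.integer(trials_per_cell), nrow(cells)),
                             dp$drift_v, dp$boundary_a, s)
    trials <- data.frame(
      participant_id = rep(cells$participant_id, each = trials_per_cell),
      prev_congruency = rep(cells$prev_congruency, each = trials_per_cell),
      congruency = rep(cells$congruency, each = trials_per_cell),
      rt = smp$rt + rep(dp$ter, each = trials_per_cell),
      correct = smp$upper,
      is_contaminant = 0L,
      trial_index = rep(seq_len(trials_per_cell), nrow(cells))
    )
    trials <- inject_contaminants(trials, contaminant_rate,
                                  contaminant_lo, contaminant_hi)
    attr(trials, "effect_label") <- params$label
    attr(trials, "seed") <- seed
    attr(trials, "attempts") <- attempt
    attr(trials, "n_ter_floored") <- n_floored
    return(trials)
  }
  stop("failed to generate a non-degenerate dataset in ", max_attempts,
       " attempts", call. = FALSE)
}
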