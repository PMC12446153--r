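#' Filter and test code tables
#'
#' `default_filter_codes()` returns the ten outlier-filtering strategies of
#' the decision tree; `default_test_codes()` the five hypothesis-testing
#' models.
#'
#' @return character vector of codes.
#' @export
default_filter_codes <- function() {
  c("sd2", "sd2.5", "sd3", "mad2", "mad2.5", "mad3",
    "fix1000", "fix1250", "fix1500", "none")
}

#' @rdname default_filter_codes
#' @export
default_test_codes <- function() {
  c("anova", "lmm", "lmm_cx", "loglmm", "loglmm_cx")
}

#' Parse an outlier-filter code
#'
#' Valid codes: `"sd2"`, `"sd2.5"`, `"sd3"` (mean +/- k SD of the
#' participant-by-condition cell), `"mad2"`, `"mad2.5"`, `"mad3"` (median
#' +/- k scaled MAD of the cell), `"fix1000"`, `"fix1250"`, `"fix1500"`
#' (fixed 200--1000/1250/1500 ms bounds) and `"none"`.
#'
#' @param code a single filter code string, or an existing `filter_spec`.
#' @return a `filter_spec` list with fields `code`, `family` (`"sd"`,
#'   `"mad"`, `"fixed"` or `"none"`), `k`, and `lo_ms`/`hi_ms`.
#' @export
filter_spec <- function(code) {
  if (inherits(code, "filter_spec")) return(code)
  stopifnot(is.character(code), length(code) == 1L)
  spec <- switch(code,
    "sd2"     = list(family = "sd", k = 2),
    "sd2.5"   = list(family = "sd", k = 2.5),
    "sd3"     = list(family = "sd", k = 3),
    "mad2"    = list(family = "mad", k = 2),
    "mad2.5"  = list(family = "mad", k = 2.5),
    "mad3"    = list(family = "mad", k = 3),
    "fix1000" = list(family = "fixed", lo_ms = 200, hi_ms = 1000),
    "fix1250" = list(family = "fixed", lo_ms = 200, hi_ms = 1250),
    "fix1500" = list(family = "fixed", lo_ms = 200, hi_ms = 1500),
    "none"    = list(family = "none"),
    stop("unknown filter code '", code, "'; valid codes: ",
         paste(default_filter_codes(), collapse = ", "), call. = FALSE)
  )
  spec$code <- code
  structure(spec, class = "filter_spec")
}

#' Parse a hypothesis-test code
#'
#' Valid codes: `"anova"` (2x2 repeated-measures ANOVA on per-participant
#' cell means), `"lmm"` (raw-RT mixed model, random intercept), `"lmm_cx"`
#' (raw RT, random intercept + congruency slope), `"loglmm"` and
#' `"loglmm_cx"` (the same two models on log RT).
#'
#' @param code a single test code string, or an existing `test_spec`.
#' @return a `test_spec` list with fields `code`, `kind`, `log` and `slope`.
#' @export
test_spec <- function(code) {
  if (inherits(code, "test_spec")) return(code)
  stopifnot(is.character(code), length(code) == 1L)
  kinds <- c(anova = "rm_anova", lmm = "lmm_simple", lmm_cx = "lmm_complex",
             loglmm = "lmm_log_simple", loglmm_cx = "lmm_log_complex")
  if (!code %in% names(kinds))
    stop("unknown test code '", code, "'; valid codes: ",
         paste(default_test_codes(), collapse = ", "), call. = FALSE)
  structure(list(code = code, kind = unname(kinds[code]),
                 log = grepl("^loglmm", code),
                 slope = grepl("_cx$", code)),
            class = "test_spec")
}

#' Define a multiverse simulation plan
#'
#' A plan fixes the study conditions: which effect types to simulate, the
#' sample sizes, the number of replicate datasets per cell, trials per
#' condition, the contaminant settings, and the filter/test grid. The
#' default plan is the full design: 4 effect types x 5 sample sizes
#' (25--400) x 1000 replicates, 100 trials per condition per participant,
#' all 10 filters and all 5 tests -- 20,000 datasets and 1,000,000
#' analyses. Desk-scale runs simply reduce `replicates` (and, if wanted,
#' the grids); nothing else changes.
#'
#' @param effect_types character vector of profile labels (resolved through
#'   [cse_profile()] unless supplied in `profiles`).
#' @param sample_sizes participants per dataset (positive integers).
#' @param replicates datasets per effect type x sample size cell.
#' @param trials_per_cell trials per condition per participant (>= 2).
#' @param filters,tests character vectors of filter/test codes.
#' @param seed master integer seed; every dataset receives a deterministic
#'   sub-seed derived from it (see [dataset_seed()]).
#' @param contaminant_rate proportion of trials per cell replaced by
#'   uniform contaminants (default 0.05).
#' @param contaminant_lo,contaminant_hi contaminant RT bounds in seconds
#'   (default 0 and 3.09).
#' @param scaling_s diffusion scaling constant (default 0.1).
#' @param profiles optional named list of `cse_params` objects overriding
#'   the shipped profiles for matching labels.
#' @return a `multiverse_plan` object.
#' @seealso [run_multiverse()], [enumerate_pathways()], [plan_counts()].
#' @export
multiverse_plan <- function(effect_types = c("prime_probe", "flanker",
                                             "prime_probe_null",
                                             "flanker_null"),
                            sample_sizes = c(25, 50, 100, 200, 400),
                            replicates = 1000,
                            trials_per_cell = 100,
                            filters = default_filter_codes(),
                            tests = default_test_codes(),
                            seed = 1L,
                            contaminant_rate = 0.05,
                            contaminant_lo = 0,
                            contaminant_hi = 3.09,
                            scaling_s = 0.1,
                            profiles = NULL) {
  stopifnot(length(effect_types) >= 1L, is.character(effect_types))
  if (length(sample_sizes) < 1L || any(sample_sizes < 1) ||
      any(sample_sizes != round(sample_sizes)))
    stop("sample_sizes must be positive integers", call. = FALSE)
  if (replicates < 1 || replicates != round(replicates))
    stop("replicates must be a positive integer", call. = FALSE)
  if (trials_per_cell < 2)
    stop("trials_per_cell must be at least 2 (cell variances)", call. = FALSE)
  if (length(filters) < 1L || length(tests) < 1L)
    stop("filters and tests must be non-empty", call. = FALSE)
  lapply(filters, filter_spec)
  lapply(tests, test_spec)
  if (contaminant_rate < 0 || contaminant_rate > 1)
    stop("contaminant_rate must be in [0, 1]", call. = FALSE)
  if (contaminant_hi <= contaminant_lo)
    stop("contaminant_hi must exceed contaminant_lo", call. = FALSE)
  resolved <- lapply(effect_types, function(lab) {
    if (!is.null(profiles) && lab %in% names(profiles)) {
      p <- profiles[[lab]]
      stopifnot(inherits(p, "cse_params"))
      validate_cse_params(p)
      p
    } else cse_profile(lab)
  })
  names(resolved) <- effect_types
  structure(list(effect_types = effect_types,
                 sample_sizes = as.integer(sample_sizes),
                 replicates = as.integer(replicates),
                 trials_per_cell = as.integer(trials_per_cell),
                 filters = filters, tests = tests,
                 seed = as.integer(seed),
                 contaminant_rate = contaminant_rate,
                 contaminant_lo = contaminant_lo,
                 contaminant_hi = contaminant_hi,
                 scaling_s = scaling_s,
                 profiles = resolved,
                 user_profiles = profiles),
            class = "multiverse_plan")
}

#' Enumerate decision pathways
#'
#' The Cartesian product of the plan's outlier filters and hypothesis tests,
#' in deterministic (filter-major) order. The default grid yields the 50
#' pathways of the full design.
#'
#' @param plan a `multiverse_plan`, or a character vector of filter codes.
#' @param tests character vector of test codes (ignored when `plan` is a
#'   `multiverse_plan`).
#' @return data.frame with columns `filter` and `test`.
#' @export
enumerate_pathways <- function(plan, tests = default_test_codes()) {
  if (inherits(plan, "multiverse_plan")) {
    filters <- plan$filters
    tests <- plan$tests
  } else filters <- plan
  if (length(filters) < 1L || length(tests) < 1L)
    stop("filters and tests must be non-empty", call. = FALSE)
  out <- expand.grid(test = tests, filter = filters,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[, c("filter", "test")]
}

#' Size of a multiverse plan
#'
#' @param plan a `multiverse_plan`.
#' @return list with `n_pathways`, `n_datasets` and `n_analyses`.
#' @export
plan_counts <- function(plan) {
  stopifnot(inherits(plan, "multiverse_plan"))
  n_path <- length(plan$filters) * length(plan$tests)
  n_data <- length(plan$effect_types) * length(plan$sample_sizes) *
    plan$replicates
  list(n_pathways = n_path, n_datasets = n_data,
       n_analyses = n_data * n_path)
}

#' @export
print.multiverse_plan <- function(x, ...) {
  cts <- plan_counts(x)
  cat("Multiverse plan\n")
  cat("  effect types:", paste(x$effect_types, collapse = ", "), "\n")
  cat("  sample sizes:", paste(x$sample_sizes, collapse = ", "),
      "| replicates:", x$replicates,
      "| trials/cell:", x$trials_per_cell, "\n")
  cat("  filters:", paste(x$filters, collapse = ", "), "\n")
  cat("  tests:", paste(x$tests, collapse = ", "), "\n")
  cat(sprintf("  contaminants: %.1f%% per cell ~ U(%.2f, %.2f) s\n",
              100 * x$contaminant_rate, x$contaminant_lo, x$contaminant_hi))
  cat(sprintf("  => %d pathways, %d datasets, %d analyses (seed %d)\n",
              cts$n_pathways, cts$n_datasets, cts$n_analyses, x$seed))
  invisible(x)
}

#' Deterministic per-dataset sub-seed
#'
#' Derives a reproducible 31-bit sub-seed from the master seed and a set of
#' integer coordinates (effect-type index, sample-size index, replicate).
#' Every decision pathway analyses the dataset generated from the same
#' sub-seed, so all 50 pathways see bit-identical data.
#'
#' @param master master integer seed.
#' @param ... integer coordinates.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
dataset_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1 (Mersenne prime; Lehmer multiplier 48271)
  h <- (abs(as.numeric(master)) %% m) + 1
  for (x in unlist(list(...))) {
    h <- (h * 48271) %% m
    h <- (h + (abs(as.numeric(x)) %% m)) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
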