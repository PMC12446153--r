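#' Read and write trial tables
#'
#' Trial tables are written as comma-separated UTF-8 with a header and the
#' documented column order `participant_id, prev_congruency, congruency,
#' rt_s, correct, is_contaminant, trial_index` (RT in seconds). Reading
#' restores the internal representation (column `rt`, factor condition
#' codes); write-then-read round-trips values exactly up to numeric
#' printing precision (15 significant digits).
#'
#' @param trials a trial table.
#' @param path file path.
#' @return `read_trials()` returns the trial table; `write_trials()` the
#'   path, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- data.frame(participant_id = trials$participant_id,
                    prev_congruency = as.character(trials$prev_congruency),
                    congruency = as.character(trials$congruency),
                    rt_s = trials$rt,
                    correct = trials$correct,
                    is_contaminant = trials$is_contaminant,
                    trial_index = trials$trial_index)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "prev_congruency", "congruency", "rt_s",
            "correct", "is_contaminant", "trial_index")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trial table misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data.frame(participant_id = df$participant_id,
             prev_congruency = factor(df$prev_congruency,
                                      levels = c("c", "i")),
             congruency = factor(df$congruency, levels = c("C", "I")),
             rt = df$rt_s,
             correct = as.integer(df$correct),
             is_contaminant = as.integer(df$is_contaminant),
             trial_index = as.integer(df$trial_index))
}

#' Read and write cell-summary tables
#'
#' Column order: `participant_id, prev_congruency, congruency, mean_rt,
#' var_rt, accuracy, n_trials` (seconds / seconds^2).
#'
#' @param cells a cell-summary table.
#' @param path file path.
#' @export
write_cells <- function(cells, path) {
  out <- cells[, c("participant_id", "prev_congruency", "congruency",
                   "mean_rt", "var_rt", "accuracy", "n_trials")]
  out$prev_congruency <- as.character(out$prev_congruency)
  out$congruency <- as.character(out$congruency)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$prev_congruency <- factor(df$prev_congruency, levels = c("c", "i"))
  df$congruency <- factor(df$congruency, levels = c("C", "I"))
  df
}

.config_keys <- c("effect_types", "sample_sizes", "replicates",
                  "trials_per_cell", "filters", "tests", "seed",
                  "contaminant_rate", "contaminant_lo", "contaminant_hi",
                  "scaling_s", "profiles")

#' Load a run configuration
#'
#' Reads a YAML configuration and returns a validated [multiverse_plan()]
#' with defaults applied to every absent key. Unknown keys (top-level or
#' inside a profile override) are rejected with the offending field named.
#' An empty file yields the full default plan. Profile overrides live under
#' `profiles: <label>: <field>: <value>` and are applied through
#' [cse_profile()], so overridden components lose their
#' `is_default_guess` flag.
#'
#' @param path path to a YAML file.
#' @return a `multiverse_plan`.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), .config_keys)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  profiles <- NULL
  if (!is.null(cfg$profiles)) {
    profiles <- lapply(names(cfg$profiles), function(lab)
      cse_profile(lab, overrides = cfg$profiles[[lab]]))
    names(profiles) <- names(cfg$profiles)
  }
  args <- cfg[setdiff(names(cfg), "profiles")]
  if (!is.null(args$sample_sizes)) args$sample_sizes <-
    as.integer(unlist(args$sample_sizes))
  if (!is.null(args$effect_types)) args$effect_types <-
    as.character(unlist(args$effect_types))
  if (!is.null(args$filters)) args$filters <- as.character(unlist(args$filters))
  if (!is.null(args$tests)) args$tests <- as.character(unlist(args$tests))
  args$profiles <- profiles
  do.call(multiverse_plan, args)
}

#' Save a run configuration
#'
#' Serializes a plan back to YAML so that `load_config(save_config(plan))`
#' reproduces it. Only user-supplied profile overrides are written (shipped
#' defaults are implicit).
#'
#' @param plan a `multiverse_plan`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
save_config <- function(plan, path) {
  stopifnot(inherits(plan, "multiverse_plan"))
  cfg <- list(effect_types = plan$effect_types,
              sample_sizes = plan$sample_sizes,
              replicates = plan$replicates,
              trials_per_cell = plan$trials_per_cell,
              filters = plan$filters,
              tests = plan$tests,
              seed = plan$seed,
              contaminant_rate = plan$contaminant_rate,
              contaminant_lo = plan$contaminant_lo,
              contaminant_hi = plan$contaminant_hi,
              scaling_s = plan$scaling_s)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Deterministic fixtures for the test suite
#'
#' Emits small CSV fixtures: `"tiny_dataset"` (a 6-participant dataset with
#' 20 trials per cell, 480 rows), `"known_moments_cells"` (cell summaries
#' constructed with [ez_forward()] from a deterministic diffusion-parameter
#' grid, together with the generating parameters, so [ez_inverse()] must
#' recover them exactly) and `"degenerate_cells"` (cells with accuracy 1
#' and 0.5 to exercise edge correction and the drift-undefined error).
#'
#' @param kind fixture kind.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return named list of file paths, invisibly.
#' @export
make_fixture <- function(kind = c("tiny_dataset", "known_moments_cells",
                                  "degenerate_cells"),
                         dir = tempdir(), seed = 1L) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (kind == "tiny_dataset") {
    trials <- simulate_cse_dataset(cse_profile("flanker"), 6,
                                   trials_per_cell = 20, seed = seed)
    p <- file.path(dir, "tiny_dataset.csv")
    write_trials(trials, p)
    return(invisible(list(trials = p)))
  }
  if (kind == "known_moments_cells") {
    grid <- expand.grid(drift_v = c(0.15, 0.25), boundary_a = c(0.08, 0.14),
                        ter = c(0.2, 0.35))[1:8, ]
    grid <- rbind(grid, data.frame(drift_v = c(0.1, 0.3, 0.2, -0.12),
                                   boundary_a = c(0.1, 0.12, 0.16, 0.1),
                                   ter = c(0.25, 0.3, 0.28, 0.22)))
    fw <- ez_forward(grid$drift_v, grid$boundary_a, grid$ter)
    lay <- .cell_grid()
    cells <- data.frame(participant_id = rep(1:3, each = 4L),
                        prev_congruency = rep(lay$prev_congruency, 3),
                        congruency = rep(lay$congruency, 3),
                        mean_rt = fw$mean_rt, var_rt = fw$var_rt,
                        accuracy = fw$accuracy, n_trials = 200L)
    p1 <- file.path(dir, "known_moments_cells.csv")
    p2 <- file.path(dir, "known_moments_params.csv")
    write_cells(cells, p1)
    utils::write.csv(grid, p2, row.names = FALSE, quote = FALSE)
    return(invisible(list(cells = p1, params = p2)))
  }
  lay <- .cell_grid()
  cells <- data.frame(participant_id = rep(1:2, each = 4L),
                      prev_congruency = rep(lay$prev_congruency, 2),
                      congruency = rep(lay$congruency, 2),
                      mean_rt = 0.55, var_rt = 0.02,
                      accuracy = c(1, 0.95, 0.9, 0.85, 0.5, 0.95, 0.9, 0),
                      n_trials = 100L)
  p <- file.path(dir, "degenerate_cells.csv")
  write_cells(cells, p)
  invisible(list(cells = p))
}
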