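#' Sample participant-level random effects
#'
#' Draws the participant random intercept and congruency slope of the RT
#' model from a zero-mean bivariate normal with covariance `params$re_cov`,
#' and the accuracy random intercept from N(0, `acc_re_sd`^2),
#' independently of the RT effects.
#'
#' @param params a `cse_params` profile.
#' @param n number of participants (>= 1).
#' @param seed optional integer seed.
#' @return data.frame with columns `participant_id`, `u_intercept`,
#'   `u_slope` (ms) and `u_acc` (logit).
#' @export
sample_participants <- function(params, n, seed = NULL) {
  validate_cse_params(params)
  if (n < 1 || n != round(n)) stop("n must be a positive integer",
                                   call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = params$re_cov)
  u <- matrix(u, ncol = 2)
  data.frame(participant_id = seq_len(n),
             u_intercept = u[, 1],
             u_slope = u[, 2],
             u_acc = stats::rnorm(n, 0, params$acc_re_sd))
}

# Fixed cell layout per participant: cC, cI, iC, iI
# (lowercase = previous trial, uppercase = current trial; c/C congruent,
# i/I incongruent; dummy coding congruent = 0, incongruent = 1).
.cell_grid <- function() {
  data.frame(prev_congruency = factor(c("c", "c", "i", "i"),
                                      levels = c("c", "i")),
             congruency = factor(c("C", "I", "C", "I"),
                                 levels = c("C", "I")))
}

#' Stage-1 simulation: Gaussian trial RTs and binomial accuracies
#'
#' For every participant and each of the four condition cells (cC, cI, iC,
#' iI), draws `trials_per_cell` Gaussian trial RTs with cell mean
#' `beta_intercept + beta_congruency*x_cur + beta_previous*x_prev +
#' beta_interaction*x_cur*x_prev + u_intercept + u_slope*x_cur` (ms) and SD
#' `resid_sd`, and a binomial accuracy count with success probability
#' `plogis()` of the accuracy linear predictor. Trials are aggregated to
#' per-cell summaries (the inputs of the EZ transformation); RTs are
#' reported in seconds.
#'
#' @param params a `cse_params` profile.
#' @param effects participant effects from [sample_participants()].
#' @param trials_per_cell trials per condition per participant (>= 2).
#' @param seed optional integer seed.
#' @param keep_trials if `TRUE`, the Gaussian trial-level records are
#'   attached as attribute `"trials"` (columns `participant_id`,
#'   `prev_congruency`, `congruency`, `rt` in seconds, `correct`,
#'   `is_contaminant`, `trial_index`) for direct mixed-model fitting, e.g.
#'   parameter-recovery checks.
#' @return data.frame of cell summaries: `participant_id`,
#'   `prev_congruency`, `congruency`, `mean_rt` (s), `var_rt` (s^2),
#'   `accuracy`, `n_trials`; 4 rows per participant.
#' @export
simulate_stage1 <- function(params, effects, trials_per_cell = 100,
                            seed = NULL, keep_trials = FALSE) {
  validate_cse_params(params)
  if (trials_per_cell < 2)
    stop("trials_per_cell must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(effects)
  grid <- .cell_grid()
  cells <- data.frame(
    participant_id = rep(effects$participant_id, each = 4L),
    prev_congruency = rep(grid$prev_congruency, n),
    congruency = rep(grid$congruency, n)
  )
  x_cur <- as.numeric(cells$congruency == "I")
  x_prev <- as.numeric(cells$prev_congruency == "i")
  u0 <- rep(effects$u_intercept, each = 4L)
  u1 <- rep(effects$u_slope, each = 4L)
  ua <- rep(effects$u_acc, each = 4L)

  mean_ms <- params$beta_intercept + params$beta_congruency * x_cur +
    params$beta_previous * x_prev +
    params$beta_interaction * x_cur * x_prev + u0 + u1 * x_cur
  ncell <- nrow(cells)
  trials_ms <- matrix(
    stats::rnorm(ncell * trials_per_cell,
                 mean = rep(mean_ms, each = trials_per_cell),
                 sd = params$resid_sd),
    nrow = trials_per_cell)
  m <- colMeans(trials_ms)
  v <- colSums((trials_ms - rep(m, each = trials_per_cell))^2) /
    (trials_per_cell - 1)
  eta <- params$acc_intercept + params$acc_congruency * x_cur +
    params$acc_previous * x_prev +
    params$acc_interaction * x_cur * x_prev + ua
  k <- stats::rbinom(ncell, trials_per_cell, stats::plogis(eta))

  cells$mean_rt <- m / 1000
  cells$var_rt <- v / 1e6
  cells$accuracy <- k / trials_per_cell
  cells$n_trials <- trials_per_cell
  if (keep_trials) {
    attr(cells, "trials") <- data.frame(
      participant_id = rep(cells$participant_id, each = trials_per_cell),
      prev_congruency = rep(cells$prev_congruency, each = trials_per_cell),
      congruency = rep(cells$congruency, each = trials_per_cell),
      rt = as.vector(trials_ms) / 1000,
      correct = 1L,
      is_contaminant = 0L,
      trial_index = rep(seq_len(trials_per_cell), ncell)
    )
  }
  cells
}
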