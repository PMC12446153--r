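#' Edge correction for observed accuracies
#'
#' Perfect (1) or zero accuracies have infinite logits, which the EZ
#' transformation cannot use. The standard edge correction replaces them
#' with `1 - 1/(2n)` and `1/(2n)`, half a trial away from the boundary.
#'
#' @param accuracy vector of accuracy proportions.
#' @param n_trials number of trials per cell (scalar or vector).
#' @return corrected accuracies strictly inside (0, 1).
#' @export
edge_correct_accuracy <- function(accuracy, n_trials) {
  hi <- 1 - 1 / (2 * n_trials)
  lo <- 1 / (2 * n_trials)
  out <- accuracy
  out[accuracy >= 1] <- if (length(hi) == 1L) hi else hi[accuracy >= 1]
  out[accuracy <= 0] <- if (length(lo) == 1L) lo else lo[accuracy <= 0]
  out
}

#' EZ transformation: cell summaries to diffusion parameters
#'
#' Implements the EZ diffusion closed forms. With `Pc` the (edge-corrected)
#' accuracy, `L = logit(Pc)`, `VRT` the RT variance and scaling constant
#' `s`:
#' \deqn{v = sign(Pc - 1/2) \, s \, [L (L Pc^2 - L Pc + Pc - 1/2)/VRT]^{1/4}}
#' \deqn{a = s^2 L / v}
#' \deqn{T_{er} = MRT - \frac{a}{2v}\,\frac{1 - e^{-va/s^2}}{1 + e^{-va/s^2}}}
#' Accuracies below one half yield a negative drift rate (the formula's sign
#' term); an accuracy of exactly one half leaves the drift undefined and is
#' an error.
#'
#' @param accuracy accuracy proportions, strictly inside (0, 1) and not
#'   equal to 0.5 (apply [edge_correct_accuracy()] first).
#' @param mean_rt mean RT per cell, seconds.
#' @param var_rt RT variance per cell, seconds^2; must be positive.
#' @param s diffusion scaling constant (default 0.1).
#' @return data.frame with columns `drift_v`, `boundary_a`, `ter`,
#'   `scaling_s`.
#' @seealso [ez_forward()], the inverse mapping used as its oracle.
#' @export
ez_inverse <- function(accuracy, mean_rt, var_rt, s = 0.1) {
  if (is.data.frame(accuracy)) {
    df <- accuracy
    accuracy <- df$accuracy; mean_rt <- df$mean_rt; var_rt <- df$var_rt
  }
  if (any(accuracy <= 0 | accuracy >= 1))
    stop("accuracy must be strictly inside (0, 1); apply edge correction",
         call. = FALSE)
  if (any(accuracy == 0.5))
    stop("drift undefined: accuracy equals 0.5 (logit = 0)", call. = FALSE)
  if (any(var_rt <= 0)) stop("var_rt must be positive", call. = FALSE)
  if (s <= 0) stop("scaling s must be positive", call. = FALSE)
  L <- stats::qlogis(accuracy)
  x <- L * (L * accuracy^2 - L * accuracy + accuracy - 0.5) / var_rt
  v <- sign(accuracy - 0.5) * s * x^0.25
  a <- s^2 * L / v
  y <- exp(-v * a / s^2)
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  data.frame(drift_v = v, boundary_a = a, ter = mean_rt - mdt,
             scaling_s = s)
}

#' EZ forward predictions: diffusion parameters to summary moments
#'
#' Closed-form accuracy, correct-RT mean and correct-RT variance implied by
#' a simple diffusion process with drift `drift_v`, boundary separation
#' `boundary_a`, non-decision time `ter` and scaling `s` (unbiased start).
#' This is the exact inverse of [ez_inverse()] and serves as the analytic
#' oracle for the trial sampler.
#'
#' @param drift_v drift rate (nonzero).
#' @param boundary_a boundary separation (> 0).
#' @param ter non-decision time, seconds.
#' @param s diffusion scaling constant (default 0.1).
#' @return data.frame with columns `accuracy`, `mean_rt`, `var_rt`.
#' @export
ez_forward <- function(drift_v, boundary_a, ter, s = 0.1) {
  if (any(drift_v == 0))
    stop("ez_forward requires a nonzero drift rate", call. = FALSE)
  if (any(boundary_a <= 0)) stop("boundary_a must be positive", call. = FALSE)
  if (s <= 0) stop("scaling s must be positive", call. = FALSE)
  y <- exp(-drift_v * boundary_a / s^2)
  pc <- 1 / (1 + y)
  mdt <- (boundary_a / (2 * drift_v)) * (1 - y) / (1 + y)
  vdt <- (boundary_a * s^2 / (2 * drift_v^3)) *
    (1 - 2 * (boundary_a * drift_v / s^2) * y - y^2) / (1 + y)^2
  data.frame(accuracy = pc, mean_rt = mdt + ter, var_rt = vdt)
}
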