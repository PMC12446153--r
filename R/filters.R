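#' Apply an outlier-exclusion strategy to a trial table
#'
#' The SD family keeps trials within `mean +/- k*SD`, the MAD family within
#' `median +/- k*MAD`, where the centre and spread are computed within the
#' participant-by-condition cell ("conditional" statistics, the standard
#' CSE practice); `center = "condition"` pools cells across participants
#' instead, for sensitivity checks. Fixed-bound filters keep
#' `lo_ms <= rt <= hi_ms` regardless of participant. All intervals are
#' closed. `"none"` returns the input unchanged. Statistics are computed on
#' whatever rows are passed in -- after error-trial exclusion and including
#' contaminants, which are not identifiable in real data.
#'
#' @param trials a trial table (rt in seconds).
#' @param spec a filter code (see [filter_spec()]) or `filter_spec` object.
#' @param center `"cell"` (participant x condition, default) or
#'   `"condition"` (pooled across participants).
#' @param mad_constant scale factor for the MAD (default 1.4826, the
#'   normal-consistency constant; use 1 for the raw MAD).
#' @return the kept rows, with attribute `"exclusion_ledger"`: a per-cell
#'   data.frame of input/excluded counts and an `empty_after` flag.
#' @seealso [filter_ledger()]
#' @export
apply_filter <- function(trials, spec, center = c("cell", "condition"),
                         mad_constant = 1.4826) {
  spec <- filter_spec(spec)
  center <- match.arg(center)
  if (nrow(trials) == 0L) stop("trials table is empty", call. = FALSE)
  rt <- trials$rt
  cid <- .cell_id(trials)
  if (spec$family == "none") {
    keep <- rep(TRUE, length(rt))
  } else if (spec$family == "fixed") {
    keep <- rt >= spec$lo_ms / 1000 & rt <= spec$hi_ms / 1000
  } else {
    if (center == "cell") {
      id <- cid$id
      nb <- cid$n
    } else {
      id <- .cond_code(trials) + 1L
      nb <- 4L
    }
    if (spec$family == "sd") {
      ctr <- .group_stat(rt, id, nb, "mean")
      spread <- .group_stat(rt, id, nb, "sd")
    } else {
      ctr <- .group_stat(rt, id, nb, "median")
      spread <- .group_stat(rt, id, nb, "mad", mad_constant)
    }
    keep <- rt >= ctr - spec$k * spread & rt <= ctr + spec$k * spread
    keep[is.na(keep)] <- TRUE # single-trial cells: spread undefined, keep
  }
  out <- trials[keep, , drop = FALSE]
  n_in <- tabulate(cid$id, cid$n)
  n_kept <- tabulate(cid$id[keep], cid$n)
  occupied <- n_in > 0L
  lay <- c("cC", "cI", "iC", "iI")
  led <- data.frame(
    cell = paste(rep(cid$participants, each = 4L), lay,
                 sep = ".")[occupied],
    n_in = n_in[occupied],
    n_excluded = (n_in - n_kept)[occupied],
    empty_after = n_kept[occupied] == 0L)
  attr(out, "exclusion_ledger") <- led
  attr(out, "filter_code") <- spec$code
  out
}

#' Per-cell exclusion ledger of a filtered trial table
#'
#' @param trials output of [apply_filter()].
#' @return the ledger data.frame, or `NULL` if absent.
#' @export
filter_ledger <- function(trials) attr(trials, "exclusion_ledger")
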