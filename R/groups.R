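# Fast integer grouping for participant-by-condition cells. Avoids
# string-based interaction() on large trial tables; condition factors have
# fixed levels (c/i, C/I) by construction.

# 0-based condition cell code in the fixed order cC, cI, iC, iI.
.cond_code <- function(trials) {
  prev_i <- if (is.factor(trials$prev_congruency))
    unclass(trials$prev_congruency) == 2L
  else trials$prev_congruency == "i"
  cur_i <- if (is.factor(trials$congruency))
    unclass(trials$congruency) == 2L
  else trials$congruency == "I"
  2L * as.integer(prev_i) + as.integer(cur_i)
}

# Integer id of the participant-by-condition cell (1 .. 4 * n_participants)
# plus the participant level table.
.cell_id <- function(trials) {
  pid <- factor(trials$participant_id)
  list(id = (as.integer(pid) - 1L) * 4L + .cond_code(trials) + 1L,
       participants = levels(pid),
       n = 4L * nlevels(pid))
}

# Per-group statistic expanded back to row length. `fun` operates on the
# split chunks; mean/sd use closed-form rowsum arithmetic instead.
.group_stat <- function(x, id, nbins, what, mad_constant = 1.4826) {
  cnt <- tabulate(id, nbins)
  if (what %in% c("mean", "sd")) {
    s1 <- numeric(nbins)
    rs <- rowsum(x, id)
    s1[as.integer(rownames(rs))] <- rs
    m <- s1 / cnt
    if (what == "mean") return(m[id])
    s2 <- numeric(nbins)
    rs2 <- rowsum(x * x, id)
    s2[as.integer(rownames(rs2))] <- rs2
    v <- (s2 - cnt * m * m) / (cnt - 1)
    v[cnt < 2] <- NA_real_
    return(sqrt(pmax(v, 0))[id])
  }
  sp <- split(x, id)
  out <- rep(NA_real_, nbins)
  vals <- if (what == "median") vapply(sp, stats::median, 0)
  else vapply(sp, function(z)
    stats::mad(z, constant = mad_constant), 0)
  out[as.integer(names(sp))] <- vals
  out[id]
}
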