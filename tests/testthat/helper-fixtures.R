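# Shared helpers: small deterministic objects built in code.

# A minimal hand-built trial table (1 participant unless n_pp > 1).
toy_trials <- function(rts_s, prev = "c", cur = "C", pp = 1L,
                       correct = 1L) {
  n <- length(rts_s)
  data.frame(participant_id = rep_len(pp, n),
             prev_congruency = factor(rep_len(prev, n),
                                      levels = c("c", "i")),
             congruency = factor(rep_len(cur, n), levels = c("C", "I")),
             rt = rts_s,
             correct = rep_len(as.integer(correct), n),
             is_contaminant = 0L,
             trial_index = seq_len(n))
}

# Build a complete 4-cell table from per-cell RT vectors (named cC,cI,iC,iI),
# recycled across participants.
toy_dataset <- function(cell_rts, n_pp = 1L) {
  cells <- list(c("c", "C"), c("c", "I"), c("i", "C"), c("i", "I"))
  names(cells) <- c("cC", "cI", "iC", "iI")
  do.call(rbind, lapply(seq_len(n_pp), function(p)
    do.call(rbind, lapply(names(cells), function(nm)
      toy_trials(cell_rts[[nm]], cells[[nm]][1], cells[[nm]][2], pp = p)))))
}

# Noiseless profile: effectively zero trial noise and no random effects, so
# cell means equal the fixed-effect predictions exactly.
noiseless_profile <- function(base = "flanker") {
  cse_profile(base, overrides = list(re_cov = matrix(0, 2, 2),
                                     resid_sd = 1e-9, acc_re_sd = 0))
}

# Pooled binomial SE for comparing two observed rates.
rate_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)
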