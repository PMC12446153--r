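---
title: "Simulating the analytical multiverse of congruency sequence effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the analytical multiverse of congruency sequence effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(csemultiverse)
```

## The problem

The congruency sequence effect (CSE) is the reduction of the congruency
effect in an interference task (flanker, prime-probe, Stroop) after an
incongruent trial relative to after a congruent one. With per-condition
cells cC, cI, iC, iI (lowercase = previous trial, uppercase = current
trial), the raw effect is `(cI - cC) - (iI - iC)`; under 0/1 dummy coding
(congruent = 0) a CSE is a *negative* previous-by-current interaction
coefficient.

Published CSE analyses vary widely in two semi-arbitrary choices: how
outlier reaction times (RTs) are excluded, and which hypothesis-testing
model is used. This package simulates trial-level CSE data with known true
effects — including exact nulls — and pushes every dataset through all
combinations of ten filtering strategies and five testing models, so the
true-positive rate (TPR) and false-positive rate (FPR) of each of the 50
decision pathways can be measured directly.

## The generative model

Data are generated in two stages per dataset.

**Stage 1 (mixed-effects cell summaries).** Participant `j` receives random
effects `(u0_j, u1_j) ~ N(0, Sigma)` (RT intercept and congruency slope)
and an independent accuracy intercept `ua_j ~ N(0, sigma_acc^2)`. For each
of the four cells, `trials_per_cell` Gaussian trial RTs are drawn with mean
(in ms)

    b0 + b_cong * cur + b_prev * prev + b_int * cur * prev + u0_j + u1_j * cur

and SD `sigma_resid`, and a binomial accuracy count with success
probability `plogis()` of the analogous logit-scale accuracy predictor.
Only the per-cell mean, variance and accuracy move forward, mirroring a
pipeline in which fitted empirical models supply participant-level
summaries rather than raw trials.

**Stage 2 (diffusion re-expansion).** Each cell's `(accuracy, mean RT, RT
variance)` triple is mapped to drift rate `v`, boundary separation `a` and
non-decision time `Ter` with the EZ diffusion closed forms (scaling
`s = 0.1`), and `trials_per_cell` trial-level RT/correctness pairs are
drawn from the corresponding Wiener first-passage process. This restores
the realistic right skew and the speed–accuracy coupling that a Gaussian
generator lacks. Finally 5% of trials per cell are replaced by
contaminants: RTs from Uniform(0, 3.09 s) with fair-coin correctness,
modelling inattention with both implausibly fast and implausibly slow
responses.

Nullification — constructing a no-effect twin of a true-effect profile —
is implemented by setting the interaction fixed effect to exactly zero
while preserving all main effects, the random-effect structure and the
complete accuracy model. (Deriving null parameters by permutation of the
empirical data is a different route to the same target; it requires the
original raw datasets, which this engine deliberately does not consume.)

## Parameter profiles and defaults

Two reference tasks anchor the effect sizes: the prime-probe profile
carries an interaction of −20.86 ms (large effect) and the flanker profile
−14.62 ms (small effect); their `_null` twins have exactly 0. These two
coefficients are externally estimated quantities; every other generative
component is a package default chosen once to produce realistic data and
flagged `is_default_guess` in the profile metadata:

| component | default | rationale |
|---|---|---|
| RT intercept | 620 / 580 ms | typical online prime-probe / flanker means |
| congruency effect | 60 / 45 ms | typical interference costs |
| previous-trial effect | 8 / 6 ms | small post-conflict slowing |
| RE covariance | SD 80 ms (intercept), 20 ms (slope), corr .2 | plausible between-participant spread for online data |
| residual SD | 150 ms | trial-level noise of online RT data |
| accuracy logits | 3.0 intercept, −0.4/−0.3 congruency, 0.1 previous, +0.3/+0.2 interaction; RE SD 0.5 | mean accuracy ~.90–.98 per cell |

With these values a generated cell has mean correct RT around 500–750 ms
and EZ-implied non-decision times around 0.35–0.45 s, all inside the
ranges diffusion modelling treats as credible. Every component can be
overridden programmatically (`cse_profile(label, overrides = list(...))`)
or in a YAML config, so users with access to fitted covariances can
reproduce their own task exactly.

```{r}
cse_profile("prime_probe")
```

## Numerical choices

* **EZ edge cases.** Perfect-accuracy cells are edge-corrected to
  `1 - 1/(2n)` (and zero-accuracy to `1/(2n)`). Accuracy below one half
  yields a negative drift, which the formulas and the sampler handle; an
  accuracy of exactly one half leaves the drift undefined, so the whole
  replicate is regenerated from a shifted sub-seed (vanishingly rare at
  the default accuracy levels). Non-decision times that come out negative
  in very noisy cells are floored at zero and counted in an attribute.
* **Trial sampler.** Decision times are drawn by inverting the exact
  large-time series CDF of the Wiener first-passage time on a 2048-point
  quadratically spaced grid (compiled code). With an unbiased start the
  decision-time distribution is identical at both boundaries, so
  correctness is an independent Bernoulli draw with the closed-form
  absorption probability. The series normalising constant is evaluated in
  closed form, and truncation error per grid point is below 1e-14, so the
  sampler has no discretisation bias; its moments are tested against the
  EZ closed forms at 3 Monte-Carlo SEs on 1e5 trials.
* **Filters.** "Conditional" SD/MAD statistics are computed within the
  participant-by-condition cell (a pooled-across-participants mode exists
  behind `center = "condition"`); the MAD uses the 1.4826
  normal-consistency constant by default; all intervals are closed; the
  statistics see post-error-exclusion data *including* contaminants, which
  a real analyst cannot identify.
* **Hypothesis tests.** All mixed models are fitted by maximum likelihood
  (REML off), since likelihood-ratio, AIC and BIC comparisons across
  fixed-effect structures require it. The interaction's significance uses
  the Wald z test, avoiding the unsettled mixed-model df question. Any
  optimizer failure, singular fit, warning or message from either the
  alternative or the null fit marks the run non-converged; such runs are
  excluded from rate denominators rather than counted as rejections. The
  repeated-measures ANOVA uses the classical 2x2 within-subject stratum
  decomposition (each 1-df effect against its effect-by-participant
  stratum), which is algebraically identical to `aov()` with an
  `Error(pp/(prev*cur))` term but linear in the number of participants;
  the test suite verifies the identity against both `aov()` and the
  paired-t equivalence.
* **Decision rule.** Mixed-model pathways accept the CSE iff
  (ΔAIC ≥ 2 or ΔBIC ≥ 6) and LRT p < .05 and Wald p < .05 and the
  estimate is negative. The ANOVA pathway needs significance plus
  direction only. Undefined statistics (e.g. a 0/0 F on degenerate data)
  count as "no evidence", never as acceptance.
* **Seeds.** One master seed; each dataset gets a 31-bit sub-seed from a
  Lehmer-style mix of its (effect, size, replicate) coordinates, so every
  pathway analyses bit-identical data and any single dataset can be
  regenerated in isolation.
* **Intervals.** Rates are pooled by summing counts over aggregated
  factors (never by averaging rates) and interval-estimated with the
  Wilson score formula; a normal-approximation mode exists for
  comparison.

## What the generator does and does not emulate

The generator reproduces the features that matter for filter/test
behaviour: participant-level heterogeneity, right-skewed RT distributions
with a speed–accuracy trade-off, error trials, and a fixed dose of
uniform contaminants. It deliberately omits trial-order structure
(sequential dependencies, feature-transition confounds, blocks), drift or
starting-point variability beyond the simple diffusion process, and any
cross-covariance between RT and accuracy random effects. Consequently,
passing tests show that a pathway controls (or inflates) error rates
*under this generative model*; they do not certify behaviour under, say,
autocorrelated vigilance drifts. The absolute TPR/FPR levels also depend
on the default covariance components above, so desk-scale figures should
be read as calibration-order quantities, not as universal constants.

## Scale of the shipped checks

The full design (20,000 datasets, 1,000,000 analyses) is a cluster-scale
job. The package treats reduced replicate counts as first-class: the test
suite runs the null-calibration check at 1000 replicates of 25
participants (binomial envelope ±3 SE around the nominal .025 directional
rate), parameter recovery on one 200-participant stage-1 dataset, and the
qualitative pathway orderings (MAD-2 most liberal, no-filter most
conservative, log-LMM FPR above ANOVA FPR) at 70 replicates with a 2-SE
slack; `scripts/acceptance.R` uses 80 replicates at each of the five
sample sizes for the pooled ANOVA FPR and a 400-participant dataset for
recovery. At these sizes Monte-Carlo error is a few percentage points on
any single rate, which the slack terms account for explicitly.

## A small end-to-end run

```{r, eval = FALSE}
plan <- multiverse_plan(
  effect_types = c("prime_probe", "prime_probe_null"),
  sample_sizes = c(25, 100), replicates = 50,
  tests = c("anova", "lmm", "loglmm"), seed = 1)
run <- run_multiverse(plan)
summary(run, by = c("filter", "test"))
plot(run)
```

## Known limitations

* Exact counts per cell are contaminated (`round(rate * n)`), not a
  stochastic 5%; the distinction is invisible at the shipped settings but
  documented for auditability.
* The engine regenerates (rather than repairs) replicates with an
  exactly-chance cell, so at pathological parameter settings (accuracy
  forced near .5) generation can require several attempts.
* Accuracy random effects are intercept-only; there is no accuracy random
  slope.
* Generalized (inverse-Gaussian) mixed models and maximal random-effect
  structures are out of scope, as are participant-level exclusion rules.
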