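# csemultiverse

Multiverse simulation of congruency-sequence-effect (CSE) analyses: how
often do common analytical pathways find a CSE when one exists, and how
often when none does?

## The problem

The CSE is the shrinking of the congruency effect after an incongruent
trial in interference tasks (flanker, prime-probe). With condition cells
cC, cI, iC, iI (lowercase = previous trial congruency, uppercase =
current), the raw effect is `(cI - cC) - (iI - iC)`; under 0/1 dummy
coding a CSE is a **negative** previous-by-current interaction
coefficient. Published CSE studies differ in two semi-arbitrary choices —
how RT outliers are excluded and which hypothesis-testing model is used —
and those researcher degrees of freedom change both power and the
false-positive rate.

`csemultiverse` is a simulation engine for quantifying exactly that. It

1. **generates** trial-level RT/accuracy data with known true effects
   (including exact nulls) through a two-stage pipeline: a mixed-effects
   Gaussian model produces per-participant condition summaries
   (`RT_ijc = b0 + b_cong x_cur + b_prev x_prev + b_int x_cur x_prev +
   u0_j + u1_j x_cur + e`, with `(u0, u1) ~ N(0, Sigma)`); each cell's
   (accuracy, mean RT, RT variance) is converted to diffusion parameters
   `(v, a, Ter)` via the EZ closed forms and re-expanded to realistically
   skewed trials with an exact Wiener first-passage sampler; 5% of trials
   per cell become Uniform(0, 3.09 s) contaminants;
2. **analyses** every dataset through all combinations of 10 outlier
   filters (mean ± 2/2.5/3 SD, median ± 2/2.5/3 MAD, 200–1000/1250/1500 ms
   bounds, none) and 5 tests (2×2 repeated-measures ANOVA; raw-RT and
   log-RT mixed models with random intercept, or intercept + congruency
   slope, compared to interaction-free null models by likelihood ratio);
3. **summarises** per-pathway true/false-positive rates (decision rule for
   mixed models: ΔAIC ≥ 2 or ΔBIC ≥ 6, LRT p < .05, Wald p < .05, negative
   estimate) with Wilson 95% intervals on pooled counts, excluding
   non-converged fits from denominators.

The shipped effect profiles anchor the interaction at −20.86 ms
(prime-probe, large) and −14.62 ms (flanker, small); their `_null` twins
zero it exactly. The full design is 4 effect types × 5 sample sizes
(25–400) × 1000 replicates = 20,000 datasets and 1,000,000 analyses;
desk-scale runs just reduce `replicates`.

## Worked example

```r
library(csemultiverse)

plan <- multiverse_plan(
  effect_types = c("prime_probe", "prime_probe_null"),
  sample_sizes = 25, replicates = 30,
  filters = c("none", "sd3", "mad2"),
  tests = c("anova", "loglmm"), seed = 1)
run <- run_multiverse(plan)
print(run)
```

```
CSE multiverse run
  6 pathway(s) x 60 dataset(s) = 360 analyses; 100.0% converged
  pooled TPR per pathway (over effect types and sample sizes):
 filter   test n_converged  rate ci_low ci_high
   mad2 loglmm          30 0.900  0.744   0.965
   none loglmm          30 0.767  0.591   0.882
    sd3 loglmm          30 0.767  0.591   0.882
   mad2  anova          30 0.500  0.332   0.668
    sd3  anova          30 0.467  0.302   0.639
   none  anova          30 0.367  0.219   0.545
  pooled FPR per pathway (over effect types and sample sizes):
 filter   test n_converged   rate  ci_low ci_high
   mad2 loglmm          30 0.2333 0.11792   0.409
    sd3 loglmm          30 0.1667 0.07337   0.336
   mad2  anova          30 0.1000 0.03460   0.256
   none  anova          30 0.0333 0.00591   0.167
   none loglmm          30 0.0333 0.00591   0.167
    sd3  anova          30 0.0333 0.00591   0.167
```

Reading: with 25 participants and a true −20.86 ms interaction, the
log-RT mixed model after a ±2 MAD filter detects the CSE in 90% of
datasets — but on null data the same pathway "detects" one 23% of the
time, nearly ten times the nominal 2.5% directional alpha. The ANOVA
without filtering is far less powerful (37%) but keeps its false-positive
rate at the nominal level. `summary(run, by = ...)` pools counts over any
subset of factors, and `plot(run)` draws the TPR-versus-FPR scatter per
pathway.

A command-line wrapper for shell pipelines lives at
`inst/cli/csemultiverse.R` (subcommands `simulate`, `analyze`,
`summarize`, `run`; YAML configs via `load_config()`/`save_config()`).

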