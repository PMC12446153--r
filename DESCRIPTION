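Package: csemultiverse
Title: Multiverse Simulation of Congruency Sequence Effect Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates trial-level reaction-time and accuracy data for
    congruency sequence effect (CSE) experiments under known true effects
    (including exact nulls) with a two-stage generator: Gaussian
    mixed-effects cell summaries are converted to diffusion-model
    parameters through the EZ closed forms and re-expanded to trials with
    an exact Wiener first-passage sampler, plus uniform reaction-time
    contaminants. Every dataset is then pushed through all combinations of
    common outlier-filtering strategies (SD, MAD, fixed bounds, none) and
    hypothesis-testing models (repeated-measures ANOVA and four linear
    mixed-effects variants), and true- and false-positive rates are
    summarised per analytical pathway with Wilson confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    lme4,
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
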