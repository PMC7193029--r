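Package: survdelta
Title: Pseudo-R2 for Marker Predictive Accuracy in Mixture Cure Survival
    Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the predictive accuracy of a scalar marker (such as
    a polygenic risk score) for time-to-event outcomes over a fixed risk
    projection interval, under an entry-age-stratified two-component
    mixture ("cure") survival model.  The marker may act on the propensity
    of being susceptible to the event and on the dynamic of the event
    among susceptible subjects; the package computes a score-statistic
    pseudo-R2 (Delta) built from robust (Lin-Wei shifted) score residuals
    of both effects, together with partial-likelihood comparator indices
    (Nagelkerke, Xu-O'Quigley, O'Quigley-Xu-Stare), a weighted
    allele-dosage polygenic score builder, a cohort simulator for the
    mixture model and its robustness variants, and a Monte-Carlo study
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
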