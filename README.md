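# survdelta

Quantifying how well a polygenic risk score (PRS) — or any scalar marker —
predicts an incident event over a fixed risk projection interval is awkward
with the usual Cox-model pseudo-R² measures: in a cohort followed for a few
years, many subjects are simply not susceptible to the event within the
window, and a marker can act separately on *whether* a subject is
susceptible and on *when* susceptible subjects fail. `survdelta` implements
a pseudo-R² criterion, **Δ**, built for exactly this setting, for
biostatisticians and genetic epidemiologists evaluating risk scores on
time-to-event cohort data.

## The model and the criterion

The working model is an entry-age-stratified two-component mixture ("cure")
survival model on the age scale. For a subject in stratum *j* with marker
*z*, the marginal survival is

    S(a | j, z) = exp(−θ_j e^{αz}) + {1 − exp(−θ_j e^{αz})} · exp(−Λ_{0j}(a) e^{βz})

where `exp(−θ_j e^{αz})` is the probability of being non-susceptible within
the projection interval (the *tail defect*), α is the **propensity effect**
of the marker and β its **dynamic effect** among susceptible subjects.

Differentiating the log partial likelihood at the null hypothesis
α = β = 0 gives two score components per event, `U1` (propensity) and `U2`
(dynamic), each a weighted difference between the failing subject's marker
and the risk-set mean — a measure of separability. Their Lin–Wei shifted
(robust) versions `W1 = U1 − Ũ1`, `W2 = U2 − Ũ2` are i.i.d. with mean zero
under the null. Collecting the shifted scores at event times into the
2-vector `W* = (W1*, W2*)`,

    Δ = [det(Σ) − det(Σ*)] / det(Σ)

where `det(Σ)` is the generalized variance of `W*` estimated under the null
(uncentered cross-products, pooled over strata) and `det(Σ*)` under the
alternative (centered within stratum). Δ lies in [0, 1], needs no
maximisation under the alternative, and — unlike the classical
partial-likelihood indices — detects a purely dynamic effect (α = 0,
β ≠ 0). All nuisance quantities (Fleming–Harrington survival, tail defect
θ̂_j, baseline cumulative hazard Λ̂_{0j}) are estimated under the null; see
`vignette("delta-pseudo-r2")` for the details and the numerical
conventions.

The package also provides the partial-likelihood comparator indices
(Nagelkerke `N`, Xu–O'Quigley `XO`, O'Quigley–Xu–Stare `OXS`) from its own
Newton–Raphson stratified fit, a weighted allele-dosage PRS builder, a
cohort simulator for the mixture model (with Gompertz-misspecification,
Student-marker, censoring and two-strata variants) and a Monte-Carlo study
harness.

## Worked example

```r
library(survdelta)

co <- simulate_cohort(1000, tail_defect = 0.7, alpha = log(1.25),
                      beta = log(2), seed = 42)
fit <- delta_r2(survival::Surv(followup_age, event) ~ marker, data = co)
fit
#> Mixture-model pseudo-R2: Delta = 0.2079
#>   n = 1000 subjects, K = 312 events in 1 stratum/strata
#>   det(Sigma) = 1.065e+04, det(Sigma*) = 8436
```

A cohort of 1,000 subjects where 70% are non-susceptible at baseline and
the marker carries both a modest propensity effect (HR 1.25) and a dynamic
effect (HR 2) yields Δ ≈ 0.21: about a fifth of the separability variation
is explained by the marker. The comparator indices on the same cohort are
much smaller because most of the signal here is dynamic:

```r
round(ph_indices(fit_ph(co$followup_age, co$event, co$marker)), 4)
#>      N     XO    OXS
#> 0.0216 0.0216 0.0675
```

Building a PRS from the bundled *synthetic* 18-variant fixtures and feeding
it to the same pipeline:

```r
w <- read_weight_table(system.file("extdata", "synthetic_prs_weights.tsv",
                                   package = "survdelta"))
d <- read_dosage_matrix(system.file("extdata", "synthetic_dosages.csv",
                                    package = "survdelta"))
prs <- compute_prs(d, w)
round(head(prs, 3), 4)
#>   S001   S002   S003
#> 1.7008 1.8790 1.6520
```

Stratified analyses use `strata()` in the formula
(`Surv(followup_age, event) ~ marker + strata(entry_group)`), and real
age-scale cohorts with staggered entry can opt into left-truncated risk
sets via a counting-process response `Surv(entry_age, followup_age, event)`.

Command-line wrappers live in `inst/cli/`: `delta.R` (Δ and the comparator
indices for a cohort CSV, JSON output) and `simulate-study.R` (the
simulation grid).

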