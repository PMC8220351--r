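---
title: "Frailty-state transitions and care utilisation with cfstrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frailty-state transitions and care utilisation with cfstrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfstrans)
```

## The problem

Ageing cohort studies increasingly score frailty with the Clinical Frailty
Scale (CFS), a nine-level ordinal scale from 1 (very fit) to 9 (terminally
ill). When no clinician rating is available, the CFS can be scored
retrospectively from questionnaire data with a published classification tree
over six items: counts of basic and instrumental activities of daily living
requiring help, a 28-item chronic-condition count, self-rated health, a
past-week "everything was an effort" frequency item, and whether the
respondent was physically active in the past week.

`cfstrans` implements that scoring pipeline and the two analyses usually
built on it:

* **Cross-sectional**: survey-weighted means and proportions of health and
  social care utilisation by CFS category, with design-based confidence
  intervals, service counts, monthly care hours and highest-vs-lowest fold
  changes.
* **Longitudinal**: CFS categories are collapsed into three analysis states
  — *fit* (CFS1–3), *vulnerable* (CFS4) and *frail* (CFS5+) — and 2-year
  transition probabilities between these states (plus an absorbing *died*
  state) are estimated from interval-censored panel observations with a
  continuous-time multi-state Markov model.

Because the microdata that motivate the package are access-restricted, the
package also ships a first-class synthetic cohort generator that emulates the
panel structure those analyses assume. All distribution-level validation in
the test suite runs against that generator.

## The multi-state model

States are ordered (fit, vulnerable, frail, died). The chain is
time-homogeneous with generator \(Q\): off-diagonal entries are
instantaneous transition intensities (per year), rows sum to zero and the
death row is zero (absorbing). Over an interval of length \(t\) the
transition probabilities are the interval law

\[ P(t) = \exp(Qt). \]

Panel data observe the state only at interview waves, roughly two years
apart, so individual transitions are interval-censored. The likelihood of a
subject observed in state \(a\) at \(t_1\) and \(b\) at \(t_2\) is
\(P(t_2-t_1)_{ab}\); products over consecutive observation pairs and over
subjects give the full likelihood. Three conventions matter:

* **Death** is ascertained at the following wave without an exact date, so a
  death observation contributes the interval-censored term
  \(P(t_2-t_1)_{a,\mathrm{died}}\), which already sums over every path into
  death. An exact-death-time likelihood is out of scope.
* **Missing waves** are assumed missing at random and are skipped: by the
  Markov property a subject observed at waves 1 and 3 contributes a single
  4-year term. Subjects are never dropped for intermittent missingness and
  may re-enter after a missing wave.
* **Attrition weights** are used only in the cross-sectional estimates,
  not in the transitions likelihood.

`fit_msm()` maximises the likelihood over *log*-intensities (so any
parameter vector maps to a valid generator) with BFGS, starting from crude
empirical rates (observed transition counts over person-time at risk);
convergence is reported, never assumed. The matrix exponential is evaluated
by scaling-and-squaring with a truncated Taylor series, which at this 4×4
scale is faster and more robust over the optimiser's trajectory than
eigendecomposition; an independent event-time path simulator in the test
suite confirms the interval law to Monte-Carlo accuracy.

### Allowed instantaneous transitions

By default only adjacent severity moves (fit↔vulnerable, vulnerable↔frail)
plus death from every transient state carry free intensities
(`msm_mask()`); direct fit↔frail moves then arise over an interval via two
jumps. Whether the published analysis allowed direct fit↔frail intensities
is not stated, so the mask is configurable
(`msm_mask(direct_fit_frail = TRUE)`), and the Table-recovery experiment in
the acceptance suite uses the full transient mask so that the fitted model
class contains the generating process, whose calibrated generator carries
small direct fit→frail (≈0.009/y) and frail→fit (≈0.026/y) intensities.

### Calibrating a generator to a printed 2-year matrix

`nearest_generator(P, t)` takes a published interval matrix (rows
renormalised to sum to 1, since printed entries are rounded), computes the
principal matrix logarithm divided by \(t\), clips any negative
off-diagonal intensities to zero, zeroes the absorbing row and rebalances
the diagonal. The maximum entry-wise reproduction error is returned with the
generator. For the published 2-year matrix shipped as
`ref_transition_2yr()` the principal logarithm is already a valid generator,
so the reproduction error is at machine precision.

### Confidence intervals

The source analysis reports 95% confidence intervals without stating the
method, so the package's own choice is a seeded **parametric bootstrap**
(`bootstrap_ci()`): simulate replicate panels from the fitted generator over
each subject's observed observation grid (conditioning on the first observed
state; death truncates a replicate's grid), refit, and take percentile
bounds. Replicates that fail to converge are dropped and counted; more than
20% dropped is an error. Percentile bounds at small \(B\) need not bracket
the maximum-likelihood estimate, so bounds are expanded to contain the point
estimate. `B = 500` is a sensible production default; the coverage study in
the test suite uses 200 simulated datasets of 300 subjects with `B = 99`
per dataset, a deliberate problem size that keeps the whole suite fast while
leaving the binomial tolerance of the coverage check (nominal 95%, required
≥ 88%) comfortably wide.

## The classification-tree engine

Trees are plain configuration (JSON/YAML, `read_cfs_tree()` /
`write_cfs_tree()`): internal nodes test one item with an operator
(`<, <=, >=, >, ==, in`; ordinal items compare by level rank) and leaves
carry a CFS category. The engine is generic and is validated against an
independent path-walking oracle by exhaustive sweep of a discretised item
domain, so its correctness does not depend on any particular tree. The
shipped tree (`cfs_tree()`) is a transcription of the published tree's
*structure* — basic-ADL dependency drives CFS6–7, instrumental-ADL
dependency CFS5, symptom burden (effort, fair/poor self-rated health) CFS4,
and activity, condition count and self-rated health separate CFS1–3. Its
thresholds live in `inst/extdata/cfs_tree.json`, and users scoring real data
should review them against the published instrument. The engine supports
CFS8–9 leaves even though community panels rarely observe them.
`validate_tree()` reports structural issues and categories with empty
preimages; `tree_preimage()` / `generate_items()` enumerate leaf regions and
sample item vectors uniformly within them — the exact inverse of scoring,
which is what lets the simulator attach item vectors that provably classify
back to their assigned category.

Item derivation (`derive_item_vector()`) performs no imputation: a missing
required field is an error. Ordinal labels are matched case-insensitively
and the full questionnaire phrasings of the effort item are accepted as
aliases, because questionnaire exports vary in casing. The BADL/IADL item
lists are configurable (the source instrument does not enumerate them);
the defaults are the six Katz basic and eight Lawton instrumental
activities, and the help-needed (rather than any-difficulty) reading of
those flags is an assumption documented here rather than a fact of the
instrument.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the study conditions the analyses assume:
3,500 subjects aged 65+, five waves two years apart, baseline categories
drawn from the published prevalence vector (`ref_prevalence_wave5()`,
normalised), state dynamics driven by the generator calibrated to the
published 2-year matrix, 5% per-wave missingness (missing at random, wave 0
always observed, death always ascertained), lognormal mean-1 attrition
weights (sdlog 0.5: strictly positive and right-skewed, like survey
weights), and category-conditional utilisation distributions whose means
interpolate the published endpoints (GP visits 2.5→5.9, outpatient 0.7→3.9,
ED 0.1→0.9, admissions 0.2→1.0, hospital nights 6.6→26.1, mean services
count 0.3→2.0 spread evenly over the 13 services) and whose care-hour
targets follow the published per-category pattern, including that mild
frailty receives no paid non-state care and the unpaid share of non-state
care is about 100/71/75% for the three frail categories. Counts are Poisson
by default (negative-binomial dispersion is configurable), hours-per-day are
gamma, days-per-month binomial on 0–30.

Between waves the state evolves by **one multinomial draw per interval**
from the interval law — sufficient because the estimator itself treats all
transitions (including death) as interval-censored, so event-time path
simulation would add cost without changing any fitted quantity. Categories
within a state are re-drawn each wave from the baseline mix conditioned on
the state; whole waves (not single items) go missing.

Deliberate simplifications, which bound what passing tests can show about
real data: missingness is independent of state (real attrition is likely
informative), intensities carry no age/sex effects and no time
inhomogeneity, utilisation variables are drawn independently given the
category (real admissions and nights in hospital are correlated), weights
are constant within subject, and wave spacing is exactly biennial unless
per-interval spacings are supplied.

## Numerical choices and degenerate inputs

* Log-intensities are clamped at `exp(6)` per year inside the optimiser to
  keep the matrix exponential finite on wild excursions; the bound is far
  above any plausible frailty transition rate.
* Interval lengths are grouped by 10 significant digits, so each unique gap
  costs one matrix exponential per likelihood evaluation.
* An observed transition that is impossible under structural zeros yields a
  `-Inf` log-likelihood with a diagnostic listing the offending
  transitions.
* `nearest_generator()` refuses matrices with an eigenvalue on the closed
  negative real axis (no real principal logarithm).
* An empty panel has log-likelihood 0; a panel with no observed transitions
  cannot be fitted; free intensities with no directly observed transitions
  are reported in the fit object.
* Tiny negative entries left by the truncated Taylor series are clipped and
  rows renormalised, so every emitted matrix is exactly row-stochastic.

## Worked example

```{r example}
cfg <- sim_config(n_subjects = 800, seed = 42)
panel <- simulate_cohort(cfg)

# score a raw questionnaire record
raw <- c(
  as.list(setNames(rep(FALSE, 28), paste0("cond_", cfs_conditions()))),
  as.list(setNames(rep(FALSE, 6), paste0("badl_", katz_badl()))),
  as.list(setNames(rep(FALSE, 8), paste0("iadl_", lawton_iadl()))),
  list(self_rated_health = "very good",
       effort_frequency = "rarely or none of the time",
       active_past_week = TRUE)
)
classify_cfs(derive_item_vector(raw))

# fit 2-year transition probabilities with bootstrap intervals
fit <- fit_msm(as_state_panel(panel))
fit <- bootstrap_ci(fit, B = 100, seed = 1)
print(fit)

# weighted utilisation by category and flows between states
head(utilisation_summary(panel, c("gp_visits", "services_total")))
head(flow_table(panel, level = "state"))
```

## Limitations

The package fits time-homogeneous models without covariates or hidden-state
misclassification; it consumes attrition weights as given and does not
derive them; and the shipped tree is a configuration to be reviewed, not a
clinical instrument. The CFS itself is validated only in people aged 65 and
over, and synthetic-data results quantify estimator behaviour under the
stated generating assumptions, not the biases of any particular real cohort.
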