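---
title: "Estimating fortifiable wheat-flour and oil consumption: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fortifiable wheat-flour and oil consumption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fortintake)
```

## The problem

Large-scale food fortification programmes need to know how much of a
*fortifiable* food vehicle — industrially processed wheat flour or edible
oil that could legally carry added micronutrients — people actually eat.
Repeated 24-h dietary recalls provide individual-level reference data but
are expensive; fortification surveys therefore lean on two simplified
instruments:

* a **household food acquisition and purchase questionnaire (FAPQ)**, which
  records the amount of the raw vehicle a household last obtained and how
  long that amount usually lasts, and
* a **7-day semiquantitative food frequency questionnaire (SQ-FFQ)**, which
  records, per person, how often each of a fixed list of flour-containing
  foods was eaten in the past week and in what portion size.

This package implements all three estimators, the machinery to compare the
simplified instruments against the recall reference at the population
level, the WHO flour-intake-band fortification decision rules, and a
synthetic-data generator with known ground truth so that every step can be
validated without access to survey data.

## The three estimators

### Household acquisition with AME apportionment

The household's daily use of the vehicle is the acquired amount divided by
the reported duration it lasts; households that do not use a fortifiable
form are assigned zero. Each member then receives a share proportional to
their **adult male equivalent (AME)** — their energy requirement as a
fraction of an adult male's (18–29.9 y = 1):

$$\hat{c}_i \;=\; \frac{\mathrm{AME}_i}{\sum_{j \in \mathrm{household}} \mathrm{AME}_j}\;\times\;\frac{\text{amount obtained}}{\text{days it lasts}}.$$

The estimate is *apparent consumption*: it assumes all acquired vehicle is
eaten, at home, in proportion to energy requirements. The AME values are
configuration: the shipped `ame_table.csv` derives its bands from
FAO/WHO/UNU energy-requirement ratios, and any table partitioning ages
`[0, Inf)` per sex can be substituted (`read_ame_table()`). Ages are
accepted in years with decimal fractions (a 14.4-month-old is 1.2 y);
pregnancy/lactation adjustments are not applied; a fortifiable-using
household with a missing duration is a hard error rather than an imputed
value, because silent imputation would bias the denominator.

### SQ-FFQ quantification

For each item, daily flour is `flour-grams(portion) x frequency / 7`; a
person's intake is the sum over the 25-item list, with per-item and
per-food-group breakdowns. Frequencies above 7/week are allowed (staple
breads can be eaten several times a day), and one "usual" portion code per
item per person is assumed, matching the instrument. Frequencies are held
as numeric values rather than forced integers: field instruments record
counts, but the quantification is agnostic, and the generator exploits this
to construct responses whose implied intake equals a known target exactly —
the property that makes the noise-free recovery test sharp.

### Recall aggregation and the usual-intake adjustment

Recalled foods arrive with recipe-derived ingredient fractions per vehicle
and a fortifiable flag; vehicle grams per entry are
`amount x fraction x flag`, summed per person-day. A day with entries but
no vehicle-containing food is an explicit zero; a person-day absent from
the input is missing, not zero. Observation-plus-recall days are flagged
but pooled with recall days.

Single-day intakes overstate the spread of *usual* (long-run average)
intake because they contain within-person noise. The adjustment is an
amount-only measurement-error model in the style of the National Cancer
Institute's method for non-episodically consumed foods, re-implemented
here:

1. shift amounts by an offset and Box-Cox transform,
   $z = ((y+\delta)^\lambda - 1)/\lambda$ (log at $\lambda = 0$);
2. fit a one-way random-intercept model
   $z_{ij} = \beta_0 + u_i + \varepsilon_{ij}$,
   $u_i \sim N(0, \sigma_u^2)$, $\varepsilon_{ij} \sim N(0, \sigma_e^2)$;
3. pick $\lambda$ from a grid by maximising the profile log-likelihood of
   that model with the transformation Jacobian included, then re-estimate
   variance components by REML at the chosen $\lambda$;
4. simulate the usual-intake distribution: draw $u$, and for each draw take
   the expectation over $\varepsilon$ of the back-transformed intake by
   9-point Gauss–Hermite quadrature, flooring at zero.

Per-person estimates use the standard BLUP shrinkage
$\beta_0 + \frac{\sigma_u^2}{\sigma_u^2 + \sigma_e^2/n_i}(\bar z_i - \beta_0)$,
back-transformed through the same quadrature.

Defaults and their rationale:

* **λ grid** −1 to 1 in steps of 0.05 — the standard Box-Cox range; REML
  rather than ML for the reported components to reduce small-sample bias.
* **offset** — the amount-only model assumes positive intakes; when
  zero-intake days are present the default offset is half the minimum
  positive amount (configurable), otherwise 0.
* **Monte-Carlo draws** — 100 000 by default; below 1 000 the tail
  percentiles are unstable and a warning is raised.
* **Model fitting** — the random-intercept fits go through `lme4`; a
  method-of-moments estimator with a closed-form compound-symmetry
  likelihood is the fallback (and available via `method = "mom"`) for
  degenerate strata.
* Covariates (weekday, recall sequence) are deliberately not modelled, and
  children and mothers are always fitted separately.
* Identifiability contract: at least two persons, and at least one person
  with two or more days (otherwise $\sigma_e^2$ cannot be separated and
  fitting errors out); all-equal amounts yield a degenerate zero-variance
  model with a warning.

## Comparison machinery

The comparison of methods is population-level only — no per-person
agreement statistics, and no formal significance testing. The exclusion
order is fixed: first, within each simplified-method x group x vehicle
stratum, values more than 3 sample SDs from the stratum mean are excluded
(mean and SD computed once, a single pass; the recall stream is never
filtered); second, recall observations lacking a counterpart in the
simplified method under comparison are dropped, per method, so
FAPQ-matched and SQ-FFQ-matched recall sets can differ. Summaries report
mean, median and the 25th/75th percentiles using the linear-interpolation
(type 7) quantile convention, documented so IQRs are reproducible.
Comparisons report the ratio of means and percent differences of means and
medians, unrounded; rounding to integer percent happens only in the report
layer. Food-source decomposition expresses each food group's flour as a
percentage of the total, based on unadjusted means across persons.

## Decision rules

WHO guidance chooses the folic-acid level in flour from bands of per-capita
flour intake. Bands are half-open `[min, max)`, so a boundary intake
belongs to the upper band. The shipped `rules.yaml` carries the full WHO
folic-acid table (<75 → 5.0, 75–149 → 2.6, 150–300 → 1.3, >300 →
1.0 mg/kg) as editable configuration. `pct_to_next_band()` measures the
percent increase to the smallest band edge at or above the current intake
(an intake exactly on a boundary is 0% from it). Oil has no recommended
intake cutoffs; `recommend(x, NULL)` returns an explicit no-rule result
rather than a number.

## The synthetic-data generator

`simulate_study()` emulates the structure of an urban mother–child
fortification survey: ~120 households, each with one mother (18–49 y), one
child (12–18 mo) and 0–4 other members with uniformly drawn ages and
sexes; four scheduled recall days per child plus a fifth day (half flagged
as a 12-h observed record with 12-h recall) and two per mother; a minority
of households using raw wheat flour at home; and FFQ responses consistent
with the recall distribution up to multiplicative reporting noise.

The generative intake model is a log-normal person/day hierarchy,
$y_{ij} = \exp(\mu + u_i + \varepsilon_{ij})$ — chosen because the
amount-only adjustment assumes a transformable skewed intake, and because
it makes analytic truth (person usual intakes, population moments)
available for recovery tests. Defaults, chosen once to give realistic
orders of magnitude for an urban Southeast-Asian setting: mothers' flour
$\mu = 3.4$, oil $\mu = 1.45$ (log-grams), $\sigma_u = 0.5$,
$\sigma_e = 0.7$, children's intake one third of mothers'; 36% of
households use raw flour at home, at 17 g/day per unit of household AME;
FFQ noise 20% CV (log-normal, mean 1).

Two bias mechanisms of the household instrument are built in. For flour,
most intake reaches individuals as prepared products purchased outside the
household's raw-flour acquisitions, which the FAPQ cannot see — so the
FAPQ underestimates flour. For oil, households acquire
`1/(1 − discard fraction)` times what members consume (cooking oil
discarded or reused); with a positive discard fraction the FAPQ
overestimates oil. The discard fraction defaults to 0 and is raised
explicitly in the direction-of-bias tests. Home raw flour is allocated to
members exactly in proportion to AME, so apportionment is exactly unbiased
for the home component — deviations from AME-proportional sharing are a
real-world error source deliberately not simulated.

What the generator does *not* emulate: real food-composition data (item
flour fractions are plausible inventions), seasonality, breast-milk
intake, banded frequency instruments, non-AME intra-household allocation,
and reporting errors in the recalls themselves (recall person-day totals
reconstruct the simulated intakes exactly). Passing tests therefore
demonstrate that the estimators and the adjustment recover what their own
assumptions entitle them to — not that any instrument is unbiased on real
data, where the recall reference has its own errors.

## Validation strategy and problem sizes

The test suite validates each operation against independent oracles:
brute-force scans (AME lookup, outlier z-scores, set-difference matching,
sort-based quantiles), closed forms (log-normal and truncated-normal usual
intake at $\lambda \in \{0, 1\}$, Box-Cox round trips), and
simulation-truth recovery (500 persons x 4 days at $\lambda = 0$,
$\sigma_u = 0.5$, $\sigma_e = 0.7$; 2 000 households for population-moment
convergence; 120 households for the end-to-end property checks). These
sizes keep the full suite around ten seconds while leaving Monte-Carlo
error well inside the asserted tolerances. One measurement choice worth
noting: transformed-scale variance components are only comparable to the
generating values at the generating $\lambda$, so variance-recovery checks
pin $\lambda = 0$ while the grid-selection check runs on the full grid —
comparing a $\hat\lambda \neq 0$ fit against the $\lambda = 0$ closed form
would conflate grid resolution with estimation error.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_study(simulation_config(n_households = 120, seed = 1))

# three estimators
fapq <- estimate_fapq(sim$households, sim$acquisitions, vehicle = "wheat_flour")
ffq <- estimate_ffq(sim$ffq_responses)
daily <- person_day_totals(sim$recalls, "wheat_flour")

mothers <- daily[grepl("_m$", daily$person_id), c("person_id", "grams")]
fit <- fit_usual_intake(mothers)
dist <- usual_intake_distribution(fit, seed = 1)

# population-level comparison and a decision
rule <- default_fortification_rules()$folic_acid
recommend(dist$mean, rule)
```

## Known limitations

* The FAPQ path accepts one acquisition record per household and vehicle;
  combining multiple sources (purchases plus gifts) is upstream data
  preparation.
* The usual-intake model is amount-only: populations with many true
  never-consumers need an episodic (two-part) model, which is out of
  scope; zero days are handled through the offset instead.
* Survey weights and covariate-conditional usual-intake percentiles are
  not implemented.
* Wheat-flour-equivalent conversion of purchased products, and away-from-
  home acquisition modules for the FAPQ, are out of scope — they are the
  instrument adaptations whose absence the comparison is designed to
  expose.
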