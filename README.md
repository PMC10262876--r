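# fortintake

Estimation and comparison of **fortifiable food vehicle consumption** —
industrially processed wheat flour and edible oil that could carry added
micronutrients — from the three dietary instruments used in fortification
programme surveys:

1. **FAPQ + AME** (`estimate_fapq()`): a household food acquisition and
   purchase questionnaire. Daily household use is the amount last obtained
   divided by the duration it lasts; each member's *apparent consumption* is
   their adult-male-equivalent (AME) share of it,
   `c_i = AME_i / Σ_j AME_j × amount / days`. Non-using households are
   assigned zero.
2. **7-day SQ-FFQ** (`estimate_ffq()`): per item,
   `flour-grams(portion) × frequency / 7`, summed over a 25-item table of
   flour-containing foods with per-portion flour gram equivalents.
3. **24-h recalls** (`person_day_totals()` + `fit_usual_intake()`): recalled
   foods are decomposed via recipe fractions into person-day vehicle grams,
   then adjusted for within-person variation with an amount-only
   measurement-error model (Box-Cox transform `z = ((y+δ)^λ − 1)/λ`,
   person-level random intercept `z_ij = β0 + u_i + ε_ij`, λ chosen by
   profile likelihood, REML variance components, 9-point Gauss–Hermite
   back-transformation) to obtain the usual-intake distribution
   (`usual_intake_distribution()`) and per-person BLUPs (`shrink_person()`).

On top of the estimators the package ships the population-level comparison
machinery (single-pass 3-SD outlier exclusion for the simplified methods,
per-method matching of recall observations, type-7 summaries, ratios and
percent differences, food-source shares), the WHO flour-intake-band
folic-acid decision rules (`recommend()`, `pct_to_next_band()`), and a
synthetic mother–child survey generator with known ground truth
(`simulate_study()`) used throughout the tests.

Intended users: nutrition epidemiologists and fortification-programme
analysts who need reproducible vehicle-intake estimates from household or
individual survey instruments, or who want to study how the simplified
instruments deviate from a recall reference.

## Worked example

```r
library(fortintake)
sim <- simulate_study(simulation_config(n_households = 120, seed = 1))

fapq  <- estimate_fapq(sim$households, sim$acquisitions, vehicle = "wheat_flour")
ffq   <- estimate_ffq(sim$ffq_responses)
daily <- person_day_totals(sim$recalls, "wheat_flour")

mothers <- daily[grepl("_m$", daily$person_id), c("person_id", "grams")]
fit  <- fit_usual_intake(mothers)
dist <- usual_intake_distribution(fit, seed = 1)
dist
#> Usual-intake distribution (1e+05 draws, seed 1)
#>   mean 49.21 g/day, sd 25.97
#>     p1     p5    p10    p25    p50    p75    p90    p95    p99
#>  12.32  18.13  22.24  30.76  43.86  61.49  82.80  98.69 135.72

recommend(dist$mean, default_fortification_rules()$folic_acid)
#> folic_acid: mean intake 49.2 g/day is in band [0, 75) -> 5.0 mg/kg
#>   52% higher intake would reach the next band
```

The adjusted distribution is narrower than the raw person-day amounts
(within-person noise removed), and its mean — 49.2 g/day here — falls in
the <75 g/day WHO band, so flour would be fortified at 5.0 mg/kg of folic
acid. On the same run the household instrument sees only raw flour bought
by the minority of home-baking households (mothers' mean 4.1 g/day, a
twelve-fold underestimate), while the frequency questionnaire tracks the
recall-based mean closely (49.2 g/day): the directions of bias the
comparison machinery is built to expose.

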