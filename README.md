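# gooseshot

Shooting is widely used to reduce goose–agriculture conflict, but the
*indirect* cost of shooting — disturbance that displaces birds, inflates
their daily movement, reshuffles their activity budgets and shifts their
habitat selection — is rarely quantified, either for the quarry species
or for protected species sharing the same fields. `gooseshot` is an R
package that estimates these costs from biologging data on wintering
geese: hourly GPS fixes, tri-axial accelerometer bursts and field-level
shooting logs, for a target species (Greenland barnacle goose, GBG) and
a non-target species of conservation concern (Greenland white-fronted
goose, GWfG).

Because raw tracking data for these populations are sensitive and not
publicly available, the package includes a first-class synthetic-data
generator that reproduces the statistical structure every analysis
assumes (roost–forage movement on a farmed landscape, shooting events on
designated fields, a displacement response decaying with log distance,
behaviour-dependent accelerometer signal), so the entire pipeline is
testable end to end.

## The models

* **Displacement decay.** Around each shooting event, the step during
  the exposure window is compared with the bird's own preceding step
  (1 h / 4 km retention rule). The step-length difference is modelled as

  `ΔSL = α + β₁ ln(Dist) + β₂ Time + β₃ Time² (+ Win) + u_ind`,

  a linear mixed model per species. The *disturbance distance* is where
  the lower 95% CI of the fitted curve first crosses zero (grid search +
  bisection to 1 m).
* **Exposure.** A goose-day is shooting-disturbed if any fix in the hour
  before an event falls within the species buffer of the shot field
  centroid (in-field vs nearby as a 3-level class); rates per tracked
  day and within-winter cumulative experience follow.
* **Daily movement.** Total daily distance `TD ~ Gamma(log)`, with
  `Shot × Species × Experience`, sex, random intercepts for individual,
  winter and modal farm, and AR1 across days; a 23-model a-priori set is
  ranked by AIC.
* **Activity budgets & energetics.** ODBA per burst
  (`Σ(|x−x̄|+|y−ȳ|+|z−z̄|)/n`); a random-forest ethogram classifier
  (70/30 stratified evaluation); beta-binomial (logit) day/night budget
  models and a gamma (log) daily-ODBA model, both with AR1.
* **Habitat selection.** Weighted logistic resource-selection functions
  (used fixes weight 10, pseudoabsences weight 1, sampled 10:1 inside
  the species' 100% MCP), between shooting and non-shooting days and
  pre/post shooting within days (with distance to road), evaluated by
  ROC/AUC and confusion metrics.

Mixed models are fitted with `glmmTMB` (AR1, beta-binomial) and `lme4`;
the classifier uses `randomForest`; ROC curves use `pROC`.

## Worked example

Simulate a displacement study in which the generator's decay law is set
to the GBG estimates (intercept 1711.0 m, slope −224.3 m per log-metre),
then recover it:

```r
library(gooseshot)

st    <- simulate_displacement_study("GBG", n_birds = 30, n_events = 200,
                                     seed = 1)
pairs <- build_step_pairs(st$fixes, st$events)
#> build_step_pairs: 2986 pairs retained, 3014 combinations excluded
fit   <- fit_displacement_model(pairs, "GBG")
fit
#> <displacement_fit> GBG | 2986 pairs | winter: fixed
#>     (Intercept)         ln_dist          time_c     I(time_c^2) winter2020-2021
#>         1707.51         -220.39            0.80           -1.31           -5.63
derive_disturbance_threshold(fit)
#> $threshold_m
#> [1] 2039.125
#> $status
#> [1] "crossed"
```

The fitted intercept (1707.5 m) and log-distance slope (−220.4) recover
the generator's truth (1711.0, −224.3) well within two standard errors:
a bird at the shot field is displaced ~1.7 km, and the effect decays to
statistical undetectability around 2 km here (tight synthetic noise; on
field data the crossing sits nearer the published 1184 m).

Daily travel distances, with gamma-GLMM truth 3.14 km (undisturbed) vs
4.32 km (disturbed):

```r
gd <- simulate_goose_days(n_ind = 127, days_per_ind = 40, seed = 1)
m  <- fit_distance_model(gd, terms = c(shot = TRUE))
distance_marginal_means(m)
#>          shot  mean_km   lwr_km   upr_km
#> 1 undisturbed 3.213091 3.097991 3.332467
#> 2   disturbed 4.372038 4.164624 4.589783
```

Disturbed days carry ~1.16 km of extra travel — the energetic currency
of shooting disturbance.

`run_pipeline(sim_config(seed = 1), outdir = "out")` chains everything
(simulate → ingest → displacement → exposure → movement, budgets, ODBA,
RSF) and writes CSV/JSON reports; `make_fixtures()` writes a compact
CSV/GeoJSON dataset that trips every filter rule in the pipeline.

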