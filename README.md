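# volewatch

Quantitative analysis of long-term predator and hare monitoring in
grassland landscapes with cyclic vole populations.

In upland permanent grasslands, montane water voles (*Arvicola
amphibius*) and common voles (*Microtus arvalis*) fluctuate between near
zero and ~1,000 individuals per hectare on 5–6-year cycles, and the
local community of foxes, cats, raptors, corvids and owls responds. The
standard field design for tracking that response is a fixed roadside
itinerary driven repeatedly each season, plus interval transects and
communal ordinal scores for the voles themselves. `volewatch` implements
the full analysis chain for that design, for ecologists and wildlife
managers who need reproducible indices, densities, food-intake budgets
and inference from such monitoring series:

* **Abundance indices** — the kilometric abundance index
  (KAI = max count over a session's replicate runs / itinerary length),
  transect positive-interval proportions with bootstrap CIs, standardized
  communal scores, and the composite grassland prey index
  `x4(t) = (p_Aa + p_Ma/4) / max` with linear interpolation to session
  dates.
* **Distance sampling** — maximum-likelihood hazard-rate detection
  functions `g(x) = 1 − exp(−(x/σ)^−b)` with truncation selection, AIC
  covariate comparison, effective strip widths, densities
  `D = n/(2µL)` with lognormal CIs, and KAI→density conversion
  coefficients `1/(2µ)`.
* **Food intake** — allometric theoretical daily food intake
  (TFI = FMR(M)/(energy density × assimilation), FMR = a·M^c) aggregated
  into per-session community tables with totals, percentage shares and
  phase summaries.
* **Numerical response** — Poisson regression
  `log λ = a0 + a1 ln x1 + a2 x2 + a3 x3 + a4 x4` (effort, time, season,
  prey index) with permutation p-values, half-series mean-shift tests
  and paired-series correlation tests.
* **Spatial nulls** — Monte-Carlo randomization tests of distance to
  forests and buildings against uniform placement in the observed strip.
* **Synthetic data** — a generator producing complete datasets
  (landscape GeoJSON, count CSVs, transects, scores, ground truth) from
  known parameters, used to validate every stage end to end.

## Worked example

Simulate a 20-year monitoring scenario with known truth, then run the
main estimators on the nocturnal red fox (generated with a positive time
trend, `a2 = 0.08`, and *no* prey effect, `a4 = 0`):

```r
library(volewatch)
cfg <- scenario_config(seed = 42)
bundle <- simulate_scenario(cfg)

ses <- bundle$sessions[bundle$sessions$period == "night", ]
cnt <- bundle$counts[bundle$counts$session_id %in% ses$session_id, ]
kai <- compute_kai(ses, cnt, "red_fox")

obs <- bundle$observations[bundle$observations$species_id == "red_fox", ]
fit <- fit_detection(obs$distance, w = 300)
print(fit)
#> hazard-rate detection function (w = 300 m, n = 1201 )
#>   sigma = 142.2 m, b = 2.73, ESW = 179.4 m
#>   logLik = -6637.78, AIC = 13279.56 (2 parameters)

estimate_density(sum(obs$distance <= 300),
                 sum(ses$itinerary_length * ses$n_replicates),
                 fit, table(obs$session_id))
#> density 0.73 ind.km-2 (95% CI 0.64-0.84), coef 2.79, ESW 179 m, n=1201, L=4584.0 km
```

The effective strip half-width of 179 m gives a conversion coefficient
of 2.79: multiplying any fox KAI by 2.79 turns animals·km⁻¹ into
animals·km⁻². The fitted scale (142 m vs the generating 120 m) reflects
the generator's road-avoidance and habitat tilt — the shouldered
hazard-rate family absorbs exactly this kind of near-road deficit.

```r
gt <- bundle$ground_truth[bundle$ground_truth$species_id == "red_fox", ]
des <- data.frame(n = kai$max_count,
                  log_length = log(ses$itinerary_length[match(kai$session_id, ses$session_id)]),
                  time_index = gt$time_index[match(kai$session_id, gt$session_id)],
                  season = ses$season[match(kai$session_id, ses$session_id)],
                  prey_index = gt$prey_index[match(kai$session_id, gt$session_id)])
fit_poisson(des)
#> Poisson numerical-response model (log link), 80 sessions
#>          (Intercept) log_length time_index seasonsummer seasonautumn
#> estimate     -9.2306     3.4779     0.0529       0.1862       0.2883
#> se           10.8173     3.7064     0.0165       0.1378       0.1348
#>          seasonwinter prey_index
#> estimate       0.2504    -0.0915
#> se             0.1356     0.2008
#> logLik -176.61, r-squared 0.492

permute_coefficient(des, "time_index", n_perm = 999, seed = 1)
#> [1] 0.001
permute_coefficient(des, "prey_index", n_perm = 999, seed = 1)
#> [1] 0.655
```

The permutation tests recover the generator's design: a clearly
significant positive time trend (p = 0.001) and no prey effect
(p = 0.66) for this species.

`run_pipeline(pipeline_config(input_dir, out_dir, ...))` chains every
stage on a dataset bundle (as written by `make_fixture()`) and emits the
KAI table, prey index, coefficient/p/r² report, density table with
conversion coefficients, per-session community density/TFI snapshots and
habitat randomization summaries, plus a provenance manifest.

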