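# tempadmit

Two-stage distributed-lag non-linear modelling of daily ambient temperature
and cause-specific hospital admissions.

## The problem

Short-term associations between ambient temperature and morbidity are
non-linear (risk rises at both tails of the temperature distribution) and
delayed (cold effects in particular persist for weeks). Quantifying them
across a whole country — and asking whether they changed after a public
health intervention such as a heat-health prevention plan — requires
fitting a separate time-series model in every province and then pooling
the province-level curves. `tempadmit` implements that workflow for
epidemiologists and biostatisticians working with daily admission counts
and station temperatures:

1. **First stage** — per province, a quasi-Poisson regression of daily
   counts with a DLNM *cross-basis*: a quadratic B-spline in daily maximum
   temperature (knots at the 10th/50th/90th province percentiles) tensored
   with a natural cubic spline in lag (0–21 days, knots log-spaced at
   `21^{1/4}, 21^{1/2}, 21^{3/4}`), controlling for season (8 df/year
   natural spline × year), long-term trend (1 df/decade), weekday, holiday
   and influenza admissions:

   `log E(Y_t) = intercept + cb + dow + holiday + influenza + S1(doy, 8df):year + S2(t, 1df/decade)`

   The lag-specific coefficients are cumulated ("reduced") over lags 0–21
   to the overall cumulative exposure–response curve.
2. **Second stage** — multivariate random-effects meta-analysis of the
   reduced coefficient vectors (REML over a log-Cholesky parameterization
   of the between-province covariance), BLUPs per province, the pooled
   curve on the percentile grid, the minimum-hospitalizations percentile
   (MHP), and percent changes `100·(RR − 1)` at the 1st percentile
   ("cold") and the 99th ("heat") versus the MHP.
3. **Period comparison** — the panel split into two calendar periods
   (dropping an anomalously hot year from both), each analysed separately,
   compared by a Wald test `(θ_a − θ_b)' (V_a + V_b)^{-1} (θ_a − θ_b)` on
   χ² with 5 df.
4. **Heat-wave / plan-activation analysis** — province thresholds (95th
   percentiles of summer tmax and tmin), daily risk levels 0–3 from
   forward five-day exceedance counts, relative heat-wave definitions
   (≥2/3/4 consecutive days over the 90–97.5th percentile), a
   summer-restricted indicator regression replacing the cross-basis, and
   univariate random-effects pooling of the indicator effects.

A synthetic multi-province generator with a known exposure–lag–response
surface (smooth V shape anchored on province temperature percentiles,
exponentially decaying lag weights, negative-binomial counts matching the
quasi-Poisson variance law) provides ground truth for every stage.

## Worked example

```r
library(tempadmit)

cfg <- run_config(sim = list(n_provinces = 6L, years = 1997:2008, seed = 1L),
                  period1 = c(1997, 2002), period2 = c(2004, 2008),
                  exclude_years = 2003)
b <- run_full(cfg)

b$effects[, c("period", "mhp", "cold_pct", "cold_low", "cold_high",
              "heat_pct", "heat_low", "heat_high")]
#>    period mhp cold_pct cold_low cold_high heat_pct heat_low heat_high
#> 1    full  63     32.3     22.1      43.4     9.48   -0.208      20.1
#> 2 period1  63     28.2     11.4      47.5    12.75   -1.302      28.8
#> 3 period2  91     34.2     12.8      59.5     4.62   -9.120      20.4

b$full$cold
#> cold effect at percentile 1 vs MHP 63: 32.3% (22.1, 43.4)
b$comparison$p_value
#> [1] 0.34
```

Six synthetic provinces were simulated from a truth with +35% cold risk at
the 1st temperature percentile, +14% heat risk at the 99th and minimum
risk at the 75th percentile. The pooled curve estimates a 32.3% (95% CI
22.1–43.4) cold effect and a 9.5% (−0.2–20.1) heat effect versus an MHP of
63 — both intervals covering their truths at this small panel size — and
the Wald test finds no period difference (p = 0.34), as expected since
both periods share the same truth. `run_sensitivity()` repeats the
analysis over a grid of maximum lags and seasonal df; the stage functions
(`generate_panel()`, `read_panel()`, `impute_temperature()`,
`run_first_stage()`, `meta_fit()`, `pooled_curve()`, `percent_change()`,
`wald_compare()`, `estimate_thresholds()`, `classify_activation()`,
`flag_heatwaves()`, `fit_indicator_model()`, `univariate_meta()`) are all
exported for piecemeal use, and YAML configurations are supported via
`run_config(path)`.

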