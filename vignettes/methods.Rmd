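---
title: "Two-stage distributed-lag modelling of temperature and hospital admissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage distributed-lag modelling of temperature and hospital admissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tempadmit` estimates how daily ambient temperature relates to daily counts
of cause-specific hospital admissions observed over many provinces and many
years, and how that relationship changed between two calendar periods — the
design used to evaluate heat-health prevention plans, where the second
period starts after a plan's introduction. This vignette documents the
model, the tunable parameters, the synthetic-data generator, and the
numerical and design choices the package makes where the underlying
methodology leaves them open.

## The first-stage model

For each province, daily admission counts $Y_t$ are modelled by
quasi-Poisson time-series regression with a log link:

$$
\log E(Y_t) = \alpha + cb_t + \mathrm{dow}_t + \mathrm{holiday}_t +
\mathrm{influenza}_t + S_1(\mathrm{doy}_t;\,8\,\mathrm{df}) \times
\mathrm{year}_t + S_2(t;\,1\,\mathrm{df/decade})
$$

* $cb_t$ is the **cross-basis**: the distributed lag non-linear model
  (DLNM) term representing the bi-dimensional exposure–lag–response
  surface. The exposure margin is a **quadratic B-spline** of daily maximum
  temperature with three internal knots at the province's 10th, 50th and
  90th temperature percentiles and boundary knots at its observed range;
  the lag margin is a **natural cubic spline with intercept** over lags
  0–21 days with three internal knots equally spaced on the log-lag scale,
  i.e. at $21^{1/4}, 21^{1/2}, 21^{3/4} \approx 2.14, 4.58, 9.81$ days.
  The exposure basis carries no intercept (it is absorbed by the model
  intercept); the lag basis does, so lag-0 effects are identifiable. The
  cross-basis block has $5 \times 5 = 25$ columns; its first 21 rows lack
  full lag history and are excluded from fitting.
* Seasonality is a natural cubic spline of day-of-year with 8 df per year
  (7 interior knots equally spaced over the calendar), interacted with
  year indicators so each year gets its own seasonal curve.
* The long-term trend uses one df per decade — a single linear term for
  spans of ten years or less, a natural cubic spline otherwise. (The
  methodology is sometimes stated as "a linear term for year"; the package
  implements the df-per-decade rule and exposes `trend_df` to override it.)
* Six weekday indicators (Sunday reference), a holiday flag, and the daily
  influenza admission count complete the confounder set; the influenza
  term is dropped for respiratory outcomes, where influenza admissions are
  part of the outcome itself.

Fitting uses iteratively reweighted least squares with a deviance change
tolerance of $10^{-8}$ and at most 100 iterations (conventional GLM
defaults); the dispersion is the Pearson $\chi^2$ over residual df and
scales the coefficient covariance. Aliased columns are dropped and logged,
never fatal — year-by-season interactions alias easily on short panels. A
province is excluded (flagged, not an error) when the IRLS fails, a
cross-basis coefficient is aliased or non-finite, the cross-basis
covariance block is not positive semi-definite, or the dispersion exceeds
50; the threshold mirrors the practice of excluding provinces with
unstable fits while making the criterion explicit.

The lag-specific coefficients are then **reduced** to the overall
cumulative association: with $u_j = \sum_{l=0}^{21} B^{lag}_j(l)$, the
reduced coefficient for exposure function $i$ is $\sum_j u_j
\beta_{ij}$, with covariance transformed by the same contraction. The
reduced curve equals the sum of lag-specific curves — an identity the test
suite checks to $10^{-10}$ against brute-force summation.

## The second stage

Province-level reduced coefficient vectors $\hat\theta_i$ (dimension 5)
are pooled with an intercept-only multivariate random-effects model,

$$\hat\theta_i \sim N(\theta,\; \Psi + S_i),$$

estimated by REML over a log-Cholesky parameterization of $\Psi$ (which
guarantees positive semi-definiteness), with an analytic gradient and a
method-of-moments start; on optimizer failure the method-of-moments
estimate is used and flagged. The implementation reproduces
`metafor::rma.mv(..., struct = "UN")` to four decimals on shared inputs,
and `metafor::rma.uni(method = "REML")` in the univariate case — both are
used as independent cross-checks in the tests, never as the
implementation. Best linear unbiased predictions shrink each province
toward the pool: $\mathrm{BLUP}_i = \hat\theta + \Psi(\Psi +
S_i)^{-1}(\hat\theta_i - \hat\theta)$.

The pooled curve is evaluated on an exposure basis rebuilt from the pooled
(all provinces, all days) temperature distribution, over the integer
percentile grid 1–99. The **minimum-hospitalizations percentile (MHP)** is
the grid argmin of the pooled cumulative log relative risk; ties break
toward the median percentile, and a flat curve returns 50 with a warning.
Effects are reported as percent changes $100(e^{\Delta} - 1)$ at the 1st
percentile ("cold") and the 99th ("heat") relative to the MHP, with
delta-method normal intervals. Recentering the curve at a new reference is
an exact affine operation, so the MHP-referenced curve never requires
refitting.

Two calendar periods are compared by the Wald statistic
$W = (\hat\theta_a - \hat\theta_b)^\top (V_a + V_b)^{-1} (\hat\theta_a -
\hat\theta_b)$ on $\chi^2_5$; the periods use disjoint data and are
treated as independent. Period panels exclude the anomalously hot year
(2003 in the motivating application) from both sides, and each period's
basis knots are recomputed from its own data. A singular summed covariance
falls back to the Moore–Penrose pseudo-inverse with rank-adjusted df.

## Heat-wave and prevention-plan machinery

Province thresholds are the 95th percentiles of *summer* (June–September)
daily maximum and minimum temperature; officially published thresholds can
be supplied instead. A day *exceeds* when **both** its maximum and minimum
are above their thresholds — the plan sets thresholds on both, but because
the conjunction is a modelling choice an `"either"` mode is available
behind an argument. The daily risk level counts exceedance days in the
forward five-day window $[t, t+4]$ (observed temperatures stand in for
forecasts, appropriate for retrospective evaluation): 0 exceedances →
level 0, 1–2 → level 1, 3–4 → level 2, 5 → level 3; levels 1–3 count as
plan activation. Trailing days score only the available days, with no
imputation of the future.

Relative heat-wave definitions flag maximal runs of at least 2, 3 or 4
consecutive days with maximum temperature above the 90th, 92.5th, 95th or
97.5th percentile of the province's full historical daily-maximum series
(a summer-only variant is available, since "historical series" leaves the
window open).

The indicator analysis restricts to June 1 – September 15, replaces the
cross-basis with the binary activation (or heat-wave) indicator, limits
seasonality to 3 df per summer interacted with year, and retains a linear
year term for long-term trend (the methodology is silent on the trend term
in the summer model; including it is the conservative choice). Provinces
whose indicator is constant within the window are flagged non-converged
and excluded. The converged province log relative risks are pooled by
standard univariate random-effects meta-analysis (REML by default,
DerSimonian–Laird available), delegated to `metafor::rma.uni`, with
modified (truncated) Knapp–Hartung confidence intervals: the pooled
standard error is scaled by the observed between-province scatter but
never below the conventional inverse-variance value, with a t reference —
the recommended interval when pooling a moderate number of provinces.

## The synthetic-data generator

The generator emulates the registries the method was designed for, at the
motivating study's conditions: 50 provinces, daily series 1997–2013,
province mean maximum temperatures equally spaced over 17–26 °C (the span
reported across Spanish provincial capitals), an annual sinusoid peaking
on day-of-year 196 (mid-July), stationary AR(1) noise (coefficient 0.7,
marginal SD 2.5 °C), and a positive stochastic diurnal range. Counts
follow the first-stage model's own structure: log-linear in an annual
seasonal cycle (winter peak), weekday and holiday offsets, plus the
lag-weighted true cumulative curve; the first 21 days use truncated,
renormalized lag weights (a `lead_in` flag generates 21 extra lead-in days
instead). Count noise is negative-binomial parameterized to match the
quasi-Poisson mean–variance law $\mathrm{Var} = \phi\mu$ — quasi-likelihood
defines no generative law, and this is the standard simulation surrogate.
The default dispersion is 1.5: the real registries' dispersion is not
published, and 1.5 is a moderate, documented choice. An independent
winter-pulsed Poisson influenza series exercises the adjustment covariate.

The true association is anchored on the **percentile scale**: each
province's curve is $g(100 \cdot F_i(T))$ with $F_i$ the province's own
empirical temperature CDF, where $g$ is a smooth (C1, piecewise-quadratic)
V with $g(1) = \log 1.35$, $g(75) = 0$ and $g(99) = \log 1.14$ by default.
Because the second stage pools provinces on the percentile scale, a
percentile-anchored truth makes the pooled estimand identical across
provinces with different climates — with an absolute-temperature truth the
"cold effect" would sit at a different percentile in León than in Sevilla
and the pooled value would be a climate-weighted blend. True lag weights
decay exponentially with scale 5 days over lags 0–21. Provinces differ by
a multiplicative curve scaling $1 + \delta_i$, $\delta_i \sim N(0, 0.1)$,
so between-province heterogeneity (which the motivating literature
consistently reports) is genuinely present and $\Psi$ estimation is
exercised.

What the generator does **not** emulate: spatial correlation of weather
across provinces, age/sex-specific truth surfaces (strata are handled by
running the pipeline per stratum), influenza-temperature dependence, and
measurement artefacts of station data. Passing tests therefore demonstrate
correctness of the estimation machinery under the stated generative model,
not robustness to those real-data features.

## Validation design and problem sizes

The simulation-based checks run at sizes chosen to balance Monte-Carlo
precision against desk-scale runtime:

* *Parameter recovery*: 30 replicates of 20 provinces × 8 years with the
  default gradient and heterogeneity; pooled cold/heat CIs are required to
  cover the truth in ≥ 90% of replicates and the MHP to land within ±10
  percentiles in ≥ 80%.
* *Wald calibration*: 200 replicate pairs of 50 provinces × 2 years.
  Fifty provinces is the cross-sectional scale of the motivating study;
  two years is the smallest panel that still exercises the
  seasonality-by-year interaction. Provinces are drawn exchangeably (no
  fixed climate gradient) for this check: with a fixed gradient the
  between-province differences are systematic rather than exchangeable,
  the random-effects model over-states the replicate-to-replicate variance
  of the pooled mean, and the test becomes conservative — a real property
  of the two-stage design worth knowing, but not a size check. Even under
  exchangeability the REML-Wald test is mildly conservative at moderate
  province counts (estimating the 15 free elements of $\Psi$ from few
  coefficient vectors inflates the pooled covariance); the same behaviour
  is reproduced by `metafor::rma.mv`, i.e. it is a property of the method,
  not of this implementation.
* *Power*: 100 replicate pairs of 20 provinces × 5 years with a 0.3
  log-RR shift added at the cold tail of the second period.
* *Indicator recovery*: 30 replicates of 20 provinces × 5 years with a
  true +5% effect on activation days laid over a null temperature truth
  (so the indicator is the only signal), and 200 single-province null
  replicates for the type-I error of the indicator z-test.

## Numerical choices and degenerate inputs

* Quantile convention: type 7 (linear interpolation of the empirical CDF)
  everywhere — knot placement, percentile grids, thresholds. The
  convention is a documented choice; none is canonical.
* B-spline evaluation uses the Cox–de Boor recursion on the clamped knot
  vector, right-closed at the upper boundary so the maximum of the data is
  evaluable. Natural-spline construction applies the two second-derivative
  boundary constraints by QR projection, with linear extrapolation beyond
  the boundary.
* Exposure values outside a basis's boundary (e.g. a period-comparison
  grid exceeding one period's range) are clipped to the boundary with a
  warning.
* Temperature imputation: an isolated missing day takes the mean of its
  two neighbours; at a series boundary the single neighbour is used and
  logged distinctly; runs of ≥ 2 consecutive missing days are copied from
  the most-correlated reference station (supplied by the caller, with a
  Pearson-correlation ranking helper). Two-day gaps sit between the
  published rules ("only one value" vs "more than two consecutive days");
  they are routed to the reference rule and flagged with their own label.
* Lag-log knots are placed over $[1, 21]$; the alternative
  $[\varepsilon, 21]$ placement moves desk-scale results imperceptibly.
* The MHP grid is the integer percentiles 1–99 (no resolution is
  prescribed); ties break toward 50.
* The pooled percentile grid pools all days across provinces; averaging
  the province-specific distributions is the noted alternative.
* All-zero count series, constant indicators, aliased columns, and
  singular covariances each degrade to flags or warnings rather than
  errors, so one degenerate province never aborts a national analysis.

## Known limitations

* Standard errors are model-based; no allowance for residual
  autocorrelation beyond the seasonal structure.
* The before–after period comparison is not causal; no
  interrupted-time-series or difference-in-difference machinery is
  provided.
* The REML-Wald period test is conservative at small province counts (see
  above).
* Attributable numbers/fractions are out of scope, as is meta-regression
  on climate covariates.
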