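---
title: "Models and methods behind heatdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind heatdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatdose)
```

`heatdose` studies how long heat-sensitive devices monitored by a
cumulative temperature–time indicator (TTI) remain usable outside the cold
chain. This vignette documents the models, their assumptions, the tunable
parameters, the design choices made where the design was genuinely open,
and what the synthetic-data generator does and does not emulate. It states
no empirical result that the package's tests and `scripts/acceptance.R` do
not themselves compute.

## The indicator model

**Arrhenius lifetime.** The indicator is a chemical label whose inner
square darkens with cumulative heat exposure. We model its lifetime at
absolute temperature $T$ (kelvin; conversion uses 273.15 exactly) as

$$L(T) = L_{\mathrm{ref}}\,\exp\!\Big(\frac{E_a}{R}\Big(\frac{1}{T} -
\frac{1}{T_{\mathrm{ref}}}\Big)\Big),$$

so $\log L$ is linear in $1/T$ with slope $E_a/R$ (the *activation ratio*,
kelvin). `fit_arrhenius()` estimates the two parameters by ordinary least
squares on the calibration points; with two points the model interpolates
them exactly. The device label used in the field is specified to reach its
discard point after the equivalent of 17.2 days at 40 °C, 72.5 days at
30 °C, or 154 days at 25 °C; fitting all three (`tti_design_points`) gives
an activation ratio near $1.365 \times 10^4$ K with every lifetime
reproduced to better than 1%, which is the package default
(`default_tti_calibration()`). Fitting only the 40 °C and 25 °C points
predicts 72.4 days at 30 °C — the internal consistency check on the
printed triplet.

**Cumulative heat dose.** Exposure is integrated as the dimensionless
fraction of indicator life consumed,

$$D(t) = D_0 + \int_0^{t} \frac{\mathrm{d}t'}{L(T(t'))},$$

with discard at $D = 1$. `accumulate_dose()` treats the temperature as
piecewise-constant over each logging interval (the left value). At the
10–30 minute logging intervals of ambient loggers the quadrature choice is
immaterial (the increment per step is below $10^{-3}$ of a lifetime even
at 40 °C), so no higher-order rule is offered. The crossing time within
the final interval is located by linear interpolation. Dose is additive
over any partition of the series, which the tests verify exactly.

**Mean kinetic temperature.** `mkt()` implements

$$\mathrm{MKT} = \frac{\Delta H / R}{-\log\Big(\overline{
\exp\big(-\tfrac{\Delta H}{R\,T_i}\big)}\Big)}$$

with a log-sum-exp evaluation for numerical stability. The default
$\Delta H/R = 10^4$ K is the ICH stability convention
($\Delta H = 83.144$ kJ/mol); it is a reporting convention, deliberately
kept separate from the indicator's own fitted activation ratio
($\approx 1.36 \times 10^4$ K) — whether the physical label's effective
activation energy equals the reporting convention's is unknown, so both
are exposed as parameters. `mkt_from_daily_minmax()` applies the same
formula to pooled daily extremes (two values per day), the summary used
for per-device exposure when only daily minima/maxima are recorded; it
weights minimum and maximum equally, a crude but conventional compromise.

## From daily calendars to discard records

Field workers record each device each morning as status 1 (inner square
lighter than the outer circle), 2 (same colour — the discard point) or 3
(darker). The receipt date is time zero ($T_0$, "day 0"); the first daily
check is day 1. A transition first seen on the $k$-th check is an event at
$k$ whole days — daily interval censoring collapsed to the observation
day, matching day-resolution reporting; an event can therefore never occur
on day 0. Devices never seen at status ≥ 2 are right-censored at their
last observed day. Two data-quality rules are enforced rather than
repaired: a status regression (e.g. 2 then 1) rejects the device, and any
gap in the calendar rejects the device — partially missing calendars are
not imputed, mirroring how a month of missing forms invalidates a worker's
devices in practice. `proportion_discarded_by()` refuses data censored
before the queried day and points the user to the Kaplan–Meier estimator.

## Survival analysis

`km_estimate()` wraps the product-limit estimator (`survival::survfit`)
with events-before-censorings tie handling. For the median's 95% CI no
single convention is universal; we invert pointwise complementary
log-log (Greenwood) bands, the Brookmeyer–Crowley-style construction
(`conf.type = "log-log"`), and the choice is isolated behind
`km_estimate()` so it can be swapped.

`weibull_ph_fit()` is an own-likelihood maximum-likelihood fit of the
Weibull **proportional hazards** model

$$h(t \mid x) = \frac{k}{\lambda}\Big(\frac{t}{\lambda}\Big)^{k-1}
e^{x\beta},$$

parameterised as $(\log k, \log\lambda, \beta)$ and maximised by BFGS with
analytic gradients. Coefficients are log hazard ratios (the metric in
which field results are reported), not the accelerated-failure-time metric
of `survival::survreg`; the test suite cross-checks the two routes through
the exact mapping $\beta_{PH} = -\beta_{AFT}/\sigma$, $k = 1/\sigma$.
Cluster correlation within storage sites is handled by the Huber–White
sandwich: per-observation score vectors are summed within clusters,
$V = B\,\big(\tfrac{G}{G-1}\sum_g S_g S_g^\top\big)\,B$ with $B$ the
inverse observed information and $G$ the number of clusters. The
$G/(G-1)$ small-sample factor is one common choice among several; it is
documented here rather than hidden. Degenerate designs fail loudly:
constant covariate columns are dropped with a message, non-convergence
within the iteration cap is an error carrying the optimiser's code, and a
coefficient walking beyond $|\beta| > 12$ (hazard ratios beyond
$e^{12}$) is reported as separation — a deliberate heuristic; covariates
should be on sensible scales.

`rank_sum_test()` enumerates the exact permutation null (midranks for
ties) for combined samples up to 20 and otherwise uses the tie-corrected
normal approximation without continuity correction; the exact branch is
verified against brute-force enumeration in the tests.
`compare_phase_difference()` is a difference of means with a normal-theory
(Welch) interval; called with two scalars it returns the difference with
an NA interval.

## Simulation-based sample size

The planning question: how many devices must be observed so that the
sample median of Weibull discard times (planning values: mean 180 days,
shape 3, hence scale $180/\Gamma(4/3) \approx 201.6$ and true median
$\approx 178.4$ days) lies within ±7 days of the true median with 95%
confidence. `median_precision_sim()` simulates `reps` datasets per
candidate n (default grid 100–1,000 in steps of 10 — the grid range is
standard, the step a package choice) and reports the smallest n whose
coverage reaches the target. Choices the procedure pins down explicitly:
the sample median of an even-sized sample is the mean of the two central
order statistics; the ±7-day interval is closed at its endpoints; each
grid point draws from a counter-derived seed so reruns are reproducible
and memory stays O(n). The closed-form cross-check
`analytic_median_sample_size()` uses the asymptotic variance of the sample
median, $n = \big(z_{0.975}/(2 f(m)\,\mathrm{tol})\big)^2 \approx 577$ for
the planning values, and the simulation's answer (≈580, ±1–2 grid steps
across seeds at 10,000 replicates) agrees.

## The resupply/wastage simulator

`simulate_wastage()` models one community worker's stock. Every
`cycle_days` (default 30) a delivery of
$\lceil \text{expected use} \times (1 + \text{buffer}) \rceil$ devices
arrives; defaults are expected use 22.7 and buffer 10%, making the
delivered quantity 25 — the per-worker field allotment. Each device
carries an independent discard age drawn from the discard distribution,
with age counted from delivery (the cold chain is assumed intact up to
delivery). Daily demand (deterministic-uniform by default, with a global
fractional accumulator so non-integer expected use is honoured; Poisson
optional) consumes the usable device **closest to its discard point
first** — the use-first signal of a darkening indicator. A device whose
age passes its draw before use is removed as wastage; demand exceeding
usable stock is logged as a stock-out, not an error. The first cycle is
burn-in; its surviving stock is carried into and counted with the measured
horizon (default 24 cycles, 1,000 replicates), and the accounting identity
*supplied = used + discarded + returned + ending stock* is asserted per
replicate in the tests. No mid-cycle replacement of discarded devices is
modelled, and there is no cost or multi-echelon structure.

The discard distribution can be an empirical sample (bootstrap) or a
Weibull; because raw field records are generally unavailable, the
documented default is `weibull_from_summaries()`, which solves the two
quantile equations $F(m) = 0.5$, $F(t_a) = F_a$ in closed form. The two
field phases' printed summaries (median 43 days with 16% = 88/550
discarded by day 30; median 33 days with 34% = 196/575 by day 30) give
Weibull(3.83, 47.3 d) and Weibull(5.34, 35.3 d). Under the default policy
the simulator yields mean wastage under 10% for both, with the
cooler-phase distribution strictly lower — the ordering and bound the
acceptance script recomputes. The field study's own wastage figures
depended on an unstated usage rate and distribution form, so exact
reproduction is not attempted; the bound and ordering are the robust
claims.

## The synthetic-data generator

The generator exists so that every downstream stage is exercisable
end-to-end. What it emulates, and how its defaults were calibrated — once,
against the published study conditions, and not revisited:

- **Indoor diurnal climate** (`gen_diurnal_series()`): a deterministic
  daily cycle with minimum at 06:00 and maximum at 15:00 (two half-cosine
  arcs — a single 24 h cosine cannot place the extremes 9 h apart), plus
  stationary AR(1) reading noise. Devices were stored indoors in closed
  bags, so the diurnal amplitude (1.7 and 2.3 °C for the two presets) is
  much smaller than outdoor ranges. Site heterogeneity is a single
  additive normal offset (SD 0.8 and 1.3 °C); sites without a ceiling get
  inflated noise (×1.5), adding variance but not mean, consistent with the
  observation that ceiling absence raised temperature variability, not
  averages. The preset means/amplitudes were tuned so 23-site trials
  reproduce mean daily maxima near 28.9 °C (phase 1) and 32.8 °C
  (phase 2) and site MKT ranges of roughly 25–29 °C and 27.5–33.5 °C.
- **Shipment profiles** (`gen_shipment_profile()`): six stages
  (refrigerated air legs, a warm customs hold, a hot road leg, cold
  arrival handling) whose durations were solved so the overall MKT is
  ≈10.3 °C over 8.6 days (batch 1) and ≈12.1 °C over 13.4 days (batch 2).
- **Trials** (`gen_trial()`): 23 sites × 25 devices by default, each
  device run through the dose model on its site's series and observed
  daily. Observed field medians (43 and 33 days at site MKTs of 26–30 °C)
  are substantially shorter than the indicator's design lifetimes at
  those temperatures (≈70–120 days) imply; the cause is not identifiable
  from published summaries (pre-issue exposure, conservative indicator
  chemistry, or lot variation are all candidates). Rather than guess a
  mechanism, the generator exposes an `initial_dose` per device
  (truncated normal; preset means 0.651 and 0.55, SD 0.05) calibrated so
  the default trials' Kaplan–Meier medians match 43 and 33 days; the SD
  supplies the device-level heterogeneity that makes within-site discard
  times spread as the field data do.

What it does **not** emulate: humidity, light (devices were stored in
darkness; the indicator is ultraviolet-sensitive), within-day weather
systems beyond AR(1) noise, district-level geography beyond a fixed ±0.3 °C
offset, or any decay of the drug substance itself — the package models the
indicator, which is known to be conservative relative to oxytocin's
measured potency loss. Passing tests on synthetic trials therefore
demonstrate internal consistency of the pipeline under the stated
conditions, not external validity for any particular climate.

## Numerical choices and degenerate inputs

- Kelvin conversion uses 273.15 exactly; temperatures must lie in
  [−40, 70] °C and series must be uniformly spaced — violations name the
  offending row.
- `mkt()` uses log-sum-exp; it is permutation-invariant and bounded below
  by the arithmetic mean (equality only for constant series), both
  property-tested.
- Problem sizes in the shipped tests (e.g. 5,000-observation MLE
  recovery, 200-replicate coverage studies, 1,000-replicate wastage runs)
  were chosen to keep the full suite around a minute while leaving Monte
  Carlo error well inside the asserted tolerances.
- Ties at the daily resolution are inherent to the design; the
  Kaplan–Meier and rank-sum implementations both use standard tie
  conventions rather than jittering.

## Known limitations

- The Weibull proportional-hazards fitter targets modest covariate sets
  typical of site-characteristic analyses; it has no penalisation, so
  separable covariates are an error, not a warning.
- The median CI method and the sandwich small-sample factor are documented
  conventions, not the only defensible ones.
- The wastage simulator models a single stocking point; depot-to-facility
  networks, cost, and mid-cycle emergency resupply are out of scope.
- The generator's calibration matches first and second moments of the
  published conditions; it cannot recreate device-level exposure
  microstructure, so per-degree hazard ratios estimated from synthetic
  trials are steeper than field estimates (site MKT is their only
  systematic exposure axis).
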