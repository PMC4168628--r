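# heatdose

Oxytocin is the drug of choice against postpartum haemorrhage, but it is
heat-sensitive and nominally requires 2–8 °C storage — a serious obstacle
for community-based care in settings without a reliable cold chain. One
mitigation is to issue prefilled devices carrying a **temperature–time
indicator (TTI)**: a label whose inner square darkens with *cumulative*
heat exposure until it matches its outer circle, the signal to discard the
device. `heatdose` implements the quantitative machinery needed to study
how long such devices survive outside the cold chain and what that implies
for resupply programmes:

- **Arrhenius kinetics of the indicator.** The indicator's lifetime at
  absolute temperature $T$ follows
  $L(T) = L_{\mathrm{ref}} \exp\!\big(\tfrac{E_a}{R}(1/T - 1/T_{\mathrm{ref}})\big)$;
  `fit_arrhenius()` estimates $E_a/R$ by least squares of
  $\log L$ on $1/T$ from calibration points such as the design triplet
  17.2 d @ 40 °C, 72.5 d @ 30 °C, 154 d @ 25 °C (`tti_design_points`).
- **Cumulative heat dose.** `accumulate_dose()` integrates
  $D(t) = D_0 + \int_0^t \mathrm{d}t'/L(T(t'))$ over a logged temperature
  series; the discard point is $D = 1$.
- **Mean kinetic temperature.**
  $\mathrm{MKT} = \frac{\Delta H/R}{-\log \overline{e^{-\Delta H/(R T_i)}}}$
  with the ICH convention $\Delta H/R = 10^4$ K by default (`mkt()`,
  `mkt_from_daily_minmax()`).
- **Discard survival analysis.** Daily status calendars are validated into
  interval-collapsed discard records (`validate_calendar()`), summarised by
  Kaplan–Meier with a log(−log) median CI (`km_estimate()`), and modelled
  by Weibull proportional-hazards regression with a cluster-robust
  (Huber–White) sandwich covariance over storage sites
  (`weibull_ph_fit()`); `rank_sum_test()` compares site temperature
  summaries.
- **Simulation-based sample size.** `median_precision_sim()` finds the
  smallest n for which the sample median of Weibull data falls within a
  stated tolerance of the true median with stated confidence.
- **Resupply wastage.** `simulate_wastage()` is a Monte Carlo model of
  periodic delivery with a buffer, daily demand, use-first-to-expire
  prioritisation (the darkening indicator), and TTI-driven discard;
  `weibull_from_summaries()` reconstructs a discard distribution from a
  median and one cumulative fraction.
- **Synthetic trials.** `gen_trial()` generates full two-season field
  studies (23 sites × 25 devices, diurnal indoor climates, daily
  observation) so every stage is testable without field data.

## Worked example

```r
library(heatdose)

calib <- default_tti_calibration()
lifetime_at(calib, 30)
#> [1] 72.43364

# a synthetic dry-season trial: 23 sites x 25 devices observed daily
trial <- gen_trial(trial_config(phase = 2, seed = 1))
records <- trial_records(trial)
km_estimate(records)
#> <km_estimate> n = 575, events = 575
#>   median discard time 31 days (95% CI 30-31)

site_mkt <- vapply(trial$series, function(s) mkt(s), numeric(1))
fit <- weibull_ph_fit(records,
                      covariates = data.frame(mkt = rep(site_mkt, each = 25)))
fit$hr_table[, c("covariate", "hr", "hr_low", "hr_high")]
#>   covariate       hr   hr_low hr_high
#> 1       mkt 4.896633 4.243608 5.65015

# programme planning: monthly delivery of 25 devices (expected use + 10%)
w <- simulate_wastage(supply_policy(),
                      weibull_from_summaries(33, 30, 196 / 575),
                      horizon = 24, reps = 1000, seed = 1)
w
#> <wastage_result> 1000 reps x 24 cycles: mean wastage 7.76% (95% interval 7.46-8.13%)
```

Each degree of mean kinetic temperature multiplies the discard hazard
(here ≈4.9 per °C in a synthetic trial where between-site MKT is the only
systematic exposure difference, so the per-degree hazard ratio is steeper
than in field data with device-level exposure noise), and a monthly
resupply scheme with a 10% buffer keeps expected wastage under 10% even
for the faster-expiring hot-season discard distribution.

A thin command-line wrapper ships in `inst/cli/heatdose` with subcommands
`simulate-trial`, `fit-tti`, `mkt`, `survival`, `sample-size`, and
`wastage`, each taking `--config` (YAML), `--seed`, and `--out`.

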