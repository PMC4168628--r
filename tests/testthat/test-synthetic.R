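test_that("diurnal generator is deterministic under a seed and respects limits", {
  p <- climate_preset(NULL, daily_mean = 30, diurnal_amplitude = 0,
                      noise_sd = 0, interval_min = 30)
  s <- gen_diurnal_series(p, days = 2, seed = 1)
  expect_true(all(s$temps == 30))

  p2 <- climate_preset(1)
  a <- gen_diurnal_series(p2, site_offset = 0.5, days = 5, seed = 99)
  b <- gen_diurnal_series(p2, site_offset = 0.5, days = 5, seed = 99)
  expect_identical(a$temps, b$temps)
  expect_error(climate_preset(NULL, diurnal_amplitude = -1), "amplitude")
  expect_error(gen_diurnal_series(p2, days = 0), "days")
})

test_that("the diurnal cycle peaks mid-afternoon and bottoms at dawn", {
  p <- climate_preset(NULL, daily_mean = 28, diurnal_amplitude = 3,
                      noise_sd = 0, interval_min = 10)
  s <- gen_diurnal_series(p, days = 1, seed = 1)
  hrs <- (seq_along(s$temps) - 1) / 6
  expect_equal(hrs[which.max(s$temps)], 15)
  expect_equal(hrs[which.min(s$temps)], 6)
  expect_equal(mean(s$temps), 28, tolerance = 0.02)
})

test_that("generated series satisfy the container invariants across seeds", {
  p <- climate_preset(2)
  for (seed in 1:20) {
    s <- gen_diurnal_series(p, site_offset = rnorm(1, 0, 1.3), days = 3,
                            seed = seed)
    expect_s3_class(s, "temperature_series")
    expect_true(all(is.finite(s$temps)))
    expect_true(all(s$temps >= -40 & s$temps <= 70))
  }
})

test_that("shipment profiles concatenate stages and hit the recorded MKTs", {
  one <- data.frame(name = "cold hold", duration_days = 8.6, temp_C = 10.3,
                    temp_sd = 0)
  s <- gen_shipment_profile(one, interval_min = 30, seed = 1)
  expect_equal(mkt(s), 10.3, tolerance = 1e-9)
  expect_equal(series_duration_days(s), 8.6, tolerance = 0.02)

  # batch presets: six stages, recorded durations 8.6 / 13.4 days and
  # overall MKTs near 10.3 / 12.1 C
  st1 <- shipment_stages(1)
  expect_equal(nrow(st1), 6L)
  expect_equal(sum(st1$duration_days), 8.6, tolerance = 1e-9)
  prof1 <- gen_shipment_profile(st1, interval_min = 30, seed = 4)
  expect_equal(mkt(prof1), 10.3, tolerance = 1)

  st2 <- shipment_stages(2)
  expect_equal(sum(st2$duration_days), 13.4, tolerance = 1e-9)
  prof2 <- gen_shipment_profile(st2, interval_min = 15, seed = 4)
  expect_equal(mkt(prof2), 12.1, tolerance = 1)
  expect_error(gen_shipment_profile(one[0, ]), "nrow")
})

test_that("a default trial produces 575 analyzable device calendars", {
  trial <- gen_trial(trial_config(phase = 1, seed = 5, max_days = 100))
  expect_equal(length(trial$calendars), 23 * 25)
  expect_equal(nrow(trial$sites), 23)
  expect_equal(sum(!trial$sites$ceiling), 13)
  recs <- trial_records(trial)
  expect_equal(nrow(recs), 575)
  expect_true(all(recs$time_days >= 1))
  expect_true(all(recs$event[recs$time_days < 100] |
                    !recs$event[recs$time_days == 100]))
})

test_that("trials are reproducible and a cold climate discards nothing", {
  cfg <- trial_config(phase = 1, n_sites = 3, devices_per_site = 4,
                      seed = 77, max_days = 30)
  r1 <- trial_records(gen_trial(cfg))
  r2 <- trial_records(gen_trial(cfg))
  expect_identical(r1, r2)

  cold <- climate_preset(NULL, daily_mean = 4, diurnal_amplitude = 0,
                         site_spread_sd = 0, noise_sd = 0, interval_min = 30,
                         initial_dose_mean = 0.5, initial_dose_sd = 0)
  cfg_cold <- trial_config(phase = 1, n_sites = 2, devices_per_site = 5,
                           climate = cold, seed = 1, max_days = 60)
  recs <- trial_records(gen_trial(cfg_cold))
  expect_true(all(!recs$event))
  expect_true(all(recs$time_days == 60))
})

test_that("device calendars show 1 until the dose crossing, then 2, then 3", {
  trial <- gen_trial(trial_config(phase = 2, n_sites = 2,
                                  devices_per_site = 3, seed = 8,
                                  max_days = 90))
  cal <- trial$calendars[[1L]]
  s <- cal$statuses
  expect_true(all(diff(s) >= 0))
  first2 <- which(s >= 2)[1L]
  first3 <- which(s == 3)[1L]
  expect_false(is.na(first2))
  expect_equal(first3 - first2, trial$config$status3_lag)

  # the crossing day matches an independent dose accumulation on the site
  # series with that device's drawn initial dose removed
  rec <- validate_calendar(cal, phase = 2)
  traj <- accumulate_dose(trial$config$calib, trial$series[[cal$site_id]])
  site_dose_at_event <- traj$dose[ceiling((rec$time_days - 1) * 1440 /
                                            trial$series[[cal$site_id]]$interval_min) + 1]
  expect_true(site_dose_at_event <= 1)  # site-level dose alone cannot discard
})

test_that("no-ceiling sites show strictly higher temperature variability", {
  p <- climate_preset(1)
  with_ceiling <- gen_diurnal_series(p, days = 20, seed = 31, noise_mult = 1)
  without <- gen_diurnal_series(p, days = 20, seed = 31,
                                noise_mult = p$no_ceiling_sd_mult)
  expect_gt(sd(without$temps), sd(with_ceiling$temps))
  expect_equal(mean(without$temps), mean(with_ceiling$temps), tolerance = 0.2)
})

test_that("weibull_from_summaries solves the two quantile constraints", {
  # closed-form oracle values for the two phases' printed summaries
  w1 <- weibull_from_summaries(43, 30, 88 / 550)
  expect_equal(unname(w1["shape"]), 3.833744, tolerance = 1e-6)
  expect_equal(unname(w1["scale"]), 47.31380, tolerance = 1e-6)
  w2 <- weibull_from_summaries(33, 30, 196 / 575)
  expect_equal(unname(w2["shape"]), 5.335786, tolerance = 1e-6)
  expect_equal(unname(w2["scale"]), 35.34642, tolerance = 1e-6)

  # evaluating the constraints reproduces the inputs
  expect_equal(pweibull(43, w1["shape"], w1["scale"]), 0.5,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pweibull(30, w1["shape"], w1["scale"]), 88 / 550,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pweibull(33, w2["shape"], w2["scale"]), 0.5,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pweibull(30, w2["shape"], w2["scale"]), 196 / 575,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("weibull_from_summaries rejects degenerate or inconsistent input", {
  expect_error(weibull_from_summaries(43, 43, 0.5), "degenerate")
  expect_error(weibull_from_summaries(43, 43, 0.3), "inconsistent")
  # anchor before the median but with F > 0.5 admits no positive shape
  expect_error(weibull_from_summaries(43, 30, 0.7), "positive-shape")
  expect_error(weibull_from_summaries(43, 30, 0), "anchor_F")
})
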