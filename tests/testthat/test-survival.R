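test_that("KM on uncensored data equals one minus the empirical CDF", {
  km <- km_estimate(make_records(1:5))
  expect_equal(km$median, 3)
  expect_equal(km$surv[length(km$surv)], 0)

  set.seed(21)
  times <- sample(1:40, 200, replace = TRUE)
  km <- km_estimate(make_records(times))
  ecdf_fn <- ecdf(times)
  expect_equal(km$surv, 1 - ecdf_fn(km$time), tolerance = 1e-12)
  expect_true(all(diff(km$surv) <= 0))
  expect_equal(km_survival_at(km, 0), 1)
})

test_that("KM handles censoring and the all-censored degenerate case", {
  recs <- make_records(c(5, 10, 15, 20), event = c(TRUE, FALSE, TRUE, FALSE))
  km <- km_estimate(recs)
  # product-limit by hand: S(5) = 3/4, S(15) = 3/4 * 1/2
  expect_equal(km_survival_at(km, 5), 0.75)
  expect_equal(km_survival_at(km, 15), 0.375)
  expect_error(km_estimate(make_records(c(5, 10), event = FALSE)),
               "no discard events")
})

test_that("KM median CI matches the log-log construction on a synthetic trial", {
  set.seed(10)
  recs <- make_records(pmax(1, round(rweibull(300, 4, 45))))
  km <- km_estimate(recs)
  sf <- survival::survfit(survival::Surv(recs$time_days, recs$event) ~ 1,
                          conf.type = "log-log")
  tab <- summary(sf)$table
  expect_equal(km$median, unname(tab["median"]))
  expect_equal(km$median_ci, unname(c(tab["0.95LCL"], tab["0.95UCL"])))
})

test_that("Weibull PH MLE recovers parameters on a large uncensored sample", {
  set.seed(2)
  recs <- make_records(rweibull_ph(5000, shape = 3.8, scale = 47))
  recs$time_days <- pmax(recs$time_days, 0.5)
  fit <- weibull_ph_fit(recs)
  expect_lt(abs(fit$shape - 3.8) / 3.8, 0.02)
  expect_lt(abs(fit$scale - 47) / 47, 0.02)
  # intercept-only: scale ~ KM median / (ln 2)^(1/shape)
  km <- km_estimate(recs)
  expect_equal(fit$scale, km$median / log(2)^(1 / fit$shape), tolerance = 0.02)
})

test_that("constant covariates are dropped to an intercept-only fit", {
  set.seed(3)
  recs <- make_records(rweibull_ph(400, 3, 40))
  expect_message(
    fit <- weibull_ph_fit(recs, covariates = data.frame(flat = rep(0, 400))),
    "constant")
  expect_length(coef(fit), 0)
})

test_that("Weibull PH coefficients agree with the AFT cross-check", {
  # independent route: survreg's Weibull AFT fit, mapped to the PH metric by
  # beta_PH = -beta_AFT / sigma, shape = 1/sigma
  set.seed(4)
  n <- 800
  x <- rnorm(n)
  recs <- make_records(rweibull_ph(n, 2.5, 50, lp = 0.5 * x))
  recs$time_days <- pmax(recs$time_days, 0.25)
  cens <- recs$time_days > 60
  recs$event[cens] <- FALSE
  recs$time_days[cens] <- 60
  fit <- weibull_ph_fit(recs, covariates = data.frame(x = x))
  aft <- survival::survreg(survival::Surv(time_days, event) ~ x, data = recs,
                           dist = "weibull")
  expect_equal(unname(coef(fit)["x"]), unname(-coef(aft)["x"] / aft$scale),
               tolerance = 1e-4)
  expect_equal(fit$shape, 1 / aft$scale, tolerance = 1e-4)
  expect_equal(fit$scale, unname(exp(coef(aft)[1])), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(aft)), tolerance = 1e-6)
})

test_that("sandwich and model-based errors agree on independent data", {
  set.seed(5)
  n <- 2000
  x <- rnorm(n)
  recs <- make_records(rweibull_ph(n, 3, 45, lp = 0.3 * x))
  recs$time_days <- pmax(recs$time_days, 0.25)
  fit_iid <- weibull_ph_fit(recs, covariates = data.frame(x = x),
                            cluster = seq_len(n))
  se_model <- sqrt(diag(fit_iid$vcov_model)["x"])
  se_robust <- sqrt(diag(fit_iid$vcov)["x"])
  expect_lt(abs(se_robust - se_model) / se_model, 0.15)
})

test_that("two-group hazard ratio follows the Weibull PH scale relation", {
  # groups with scale ratio r have true HR r^(-shape)
  set.seed(6)
  shape <- 3; r <- 1.2
  n <- 4000
  g <- rep(0:1, each = n / 2)
  t <- c(rweibull(n / 2, shape, 40), rweibull(n / 2, shape, 40 * r))
  recs <- make_records(pmax(t, 0.25))
  fit <- weibull_ph_fit(recs, covariates = data.frame(g = g))
  expect_equal(unname(exp(coef(fit)["g"])), r^(-shape), tolerance = 0.1)
})

test_that("separation and non-convergence raise informative errors", {
  set.seed(7)
  recs <- make_records(rweibull(60, 3, 40))
  expect_error(weibull_ph_fit(recs, max_iter = 1), "converge")
  # a group with no events drives its log-HR to -infinity
  recs$event[1:30] <- FALSE
  sep <- data.frame(z = rep(c(1, 0), each = 30))
  expect_error(weibull_ph_fit(recs, covariates = sep, max_iter = 10000),
               "separation|converge")
})

test_that("rank-sum exact branch matches the textbook example and symmetry", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$U, 0)
  expect_equal(rs$p_value, 0.1)
  expect_equal(rs$method, "exact enumeration")

  same <- rank_sum_test(c(1, 2, 9), c(1, 2, 9))
  expect_equal(same$p_value, 1)

  shifted <- rank_sum_test(rnorm(10) + 100, rnorm(10))
  expect_lt(shifted$p_value, 0.01)
})

test_that("exact enumeration matches brute force for all small partitions", {
  brute <- function(x, y) {
    z <- c(x, y); n <- length(z); nx <- length(x)
    r <- rank(z)
    U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    mu <- nx * (n - nx) / 2
    Us <- apply(utils::combn(n, nx), 2, function(idx) {
      sum(r[idx]) - nx * (nx + 1) / 2
    })
    mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
  }
  set.seed(8)
  for (rep in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:8, nx, replace = TRUE)  # replace=TRUE forces ties
    y <- sample(1:8, ny, replace = TRUE)
    rs <- rank_sum_test(x, y)
    expect_equal(rs$p_value, brute(x, y), tolerance = 1e-12)
  }
})

test_that("the approximate branch tracks wilcox.test's tie-corrected normal p", {
  set.seed(9)
  x <- round(rnorm(30, 28, 2), 1)
  y <- round(rnorm(25, 29, 2), 1)
  rs <- rank_sum_test(x, y)
  expect_equal(rs$method, "normal approximation")
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(rs$U, unname(wt$statistic))
  expect_equal(rs$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("site temperature summaries cover the constant and preset cases", {
  s <- constant_series(30, days = 3)
  sm <- summarize_site_temps(s)
  expect_equal(sm$mean_C, 30)
  expect_equal(sm$sd_C, 0)
  expect_equal(sm$min_C, 30)
  expect_equal(sm$max_C, 30)
  expect_equal(sm$daily_max_mean_C, 30)
  expect_equal(sm$mkt_C, 30, tolerance = 1e-10)
})

test_that("phase difference of the printed maxima is exact and CIs calibrate", {
  cmp <- compare_phase_difference(32.8, 28.9)
  expect_equal(cmp$difference, 3.9)
  expect_true(all(is.na(cmp$ci)))
  expect_equal(compare_phase_difference(c(30, 31), c(30, 31))$difference, 0)

  # bootstrap oracle: percentile CI endpoints near the analytic normal CI
  set.seed(12)
  x <- rnorm(200, 32.8, 1.4)
  y <- rnorm(200, 28.9, 1.2)
  cmp <- compare_phase_difference(x, y)
  boot <- replicate(200, mean(sample(x, replace = TRUE)) -
                           mean(sample(y, replace = TRUE)))
  bci <- quantile(boot, c(0.025, 0.975))
  width <- cmp$ci[2] - cmp$ci[1]
  expect_lt(abs(bci[[1]] - cmp$ci[1]), 0.1 * width + 0.02)
  expect_lt(abs(bci[[2]] - cmp$ci[2]), 0.1 * width + 0.02)
})
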