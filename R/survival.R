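# Survival analysis of discard records: Kaplan-Meier estimate of the
# discard function, Weibull proportional-hazards regression with a
# cluster-robust (Huber-White) sandwich covariance, rank-sum comparisons of
# site temperature summaries, and the phase temperature contrast.

#' Kaplan-Meier estimate of the discard function
#'
#' Product-limit estimator of the probability that a device has not yet
#' reached the indicator's discard point by day t. Ties at the daily
#' resolution follow the standard convention (events precede censorings at
#' equal times). The median is the smallest time with survival <= 0.5; its
#' 95% CI inverts pointwise complementary log-log (Greenwood) confidence
#' bands, the Brookmeyer-Crowley-style construction.
#'
#' @param records Discard records: data.frame with `time_days` and `event`
#'   (as from [validate_calendar()] or [trial_records()]).
#' @return An object of class `km_estimate` with fields `time`, `surv`
#'   (stepwise survival after each event time), `n_risk`, `n_event`,
#'   `median`, `median_ci`, and the underlying `survival::survfit` object.
#' @export
km_estimate <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time_days", "event") %in% names(records)))
  if (!any(records$event)) {
    stopf("no discard events observed; the median is undefined")
  }
  fit <- survival::survfit(
    survival::Surv(records$time_days, records$event) ~ 1,
    conf.type = "log-log"
  )
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  ci <- unname(c(stats::quantile(fit, probs = 0.5)$lower,
                 stats::quantile(fit, probs = 0.5)$upper))
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n = sum(fit$n),
                 median = med, median_ci = ci, survfit = fit),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> n = %d, events = %d\n", x$n, sum(x$n_event)))
  if (is.na(x$median)) {
    cat("  median not reached (survival stays above 0.5)\n")
  } else {
    cat(sprintf("  median discard time %g days (95%% CI %g-%g)\n",
                x$median, x$median_ci[1L], x$median_ci[2L]))
  }
  invisible(x)
}

#' @export
plot.km_estimate <- function(x, ...) {
  graphics::plot(x$survfit, xlab = "days since receipt (T0)",
                 ylab = "proportion not yet at discard point", ...)
  invisible(x)
}

#' Survival probabilities at given times
#'
#' @param km A `km_estimate`.
#' @param times Days at which to evaluate the step function.
#' @return Survival fractions.
#' @export
km_survival_at <- function(km, times) {
  stopifnot(inherits(km, "km_estimate"))
  idx <- findInterval(times, km$time)
  c(1, km$surv)[idx + 1L]
}

# Negative log-likelihood and per-observation scores of the Weibull
# proportional-hazards model h(t) = (k/lambda) (t/lambda)^(k-1) exp(x beta),
# parameterised as theta = (log k, log lambda, beta).
weibull_ph_nll <- function(theta, t, e, X) {
  k <- exp(theta[1L]); lam <- exp(theta[2L])
  eta <- if (ncol(X)) drop(X %*% theta[-(1:2)]) else 0
  ltl <- log(t / lam)
  u <- exp(k * ltl + eta)                       # cumulative hazard
  -sum(e * (theta[1L] - log(t) + k * ltl + eta) - u)
}

weibull_ph_scores <- function(theta, t, e, X) {
  k <- exp(theta[1L]); lam <- exp(theta[2L])
  eta <- if (ncol(X)) drop(X %*% theta[-(1:2)]) else 0
  ltl <- log(t / lam)
  u <- exp(k * ltl + eta)
  d <- e - u
  cbind(logk = e + k * ltl * d,
        loglambda = -k * d,
        X * d)
}

#' Weibull proportional-hazards regression with cluster-robust errors
#'
#' Maximum-likelihood fit of the Weibull proportional-hazards model
#' `h(t | x) = (shape/scale) (t/scale)^(shape-1) exp(x beta)` (right
#' censoring handled in the likelihood), with a Huber-White sandwich
#' covariance that sums score contributions within clusters (storage sites)
#' and applies the small-sample factor G/(G-1). Coefficients are log hazard
#' ratios; `exp(beta)` is the hazard ratio with a normal-theory CI on the
#' log scale.
#'
#' @param records Discard records (`time_days`, `event`).
#' @param covariates data.frame or matrix of numeric/indicator covariates,
#'   one row per record (NULL for an intercept-only fit). Constant columns
#'   are dropped with a message.
#' @param cluster Cluster identifiers (defaults to `records$site_id`, or
#'   independent observations if absent).
#' @param conf_level Confidence level for hazard-ratio intervals.
#' @param max_iter Iteration cap for the BFGS optimiser.
#' @return An object of class `weibull_ph` with `shape`, `scale`,
#'   `coefficients` (log-HRs), `vcov` (robust), `vcov_model`, `hr_table`,
#'   `loglik`, `n`, `n_event`, `n_clusters`.
#' @export
weibull_ph_fit <- function(records, covariates = NULL, cluster = NULL,
                           conf_level = 0.95, max_iter = 200) {
  stopifnot(is.data.frame(records),
            all(c("time_days", "event") %in% names(records)))
  t <- as.numeric(records$time_days)
  e <- as.numeric(records$event)
  if (any(t <= 0)) stopf("discard times must be positive")
  if (!any(e > 0)) stopf("no events; the model is not identifiable")
  if (is.null(cluster)) {
    cluster <- if ("site_id" %in% names(records)) records$site_id
               else seq_along(t)
  }
  X <- if (is.null(covariates)) {
    matrix(numeric(0), nrow = length(t), ncol = 0)
  } else {
    as.matrix(as.data.frame(covariates))
  }
  if (ncol(X)) {
    const <- apply(X, 2L, function(col) length(unique(col)) < 2L)
    if (any(const)) {
      message("dropping constant covariate(s): ",
              paste(colnames(X)[const], collapse = ", "))
      X <- X[, !const, drop = FALSE]
    }
    if (ncol(X) && any(!is.finite(X))) stopf("non-finite covariate values")
  }
  storage.mode(X) <- "double"

  # moment-style start: exponential-rate scale at the event quantile, flat k
  theta0 <- c(log(1.2), log(stats::median(t[e > 0])) - log(log(2)) / 1.2,
              rep(0, ncol(X)))
  opt <- stats::optim(theta0, fn = weibull_ph_nll,
                      gr = function(th, t, e, X) {
                        -colSums(weibull_ph_scores(th, t, e, X))
                      },
                      t = t, e = e, X = X, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12),
                      hessian = TRUE)
  if (opt$convergence != 0) {
    stopf("Weibull PH fit did not converge after %d iterations (code %d: %s)",
          max_iter, opt$convergence,
          if (is.null(opt$message)) "no message" else opt$message)
  }
  theta <- opt$par
  if (any(abs(theta[-(1:2)]) > 12)) {
    stopf("apparent separation: a coefficient diverged during fitting")
  }
  bread <- tryCatch(solve(opt$hessian), error = function(err) {
    stopf("singular information matrix; check covariates for collinearity")
  })
  sc <- weibull_ph_scores(theta, t, e, X)
  G <- length(unique(cluster))
  Sg <- rowsum(sc, group = cluster)
  meat <- crossprod(Sg) * G / max(G - 1, 1)
  vc <- bread %*% meat %*% bread
  pn <- c("log_shape", "log_scale", colnames(X))
  dimnames(vc) <- dimnames(bread) <- list(pn, pn)
  names(theta) <- pn

  beta <- theta[-(1:2)]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  hr_table <- if (ncol(X)) {
    se <- sqrt(diag(vc)[-(1:2)])
    data.frame(covariate = colnames(X), log_hr = unname(beta),
               robust_se = unname(se), hr = exp(unname(beta)),
               hr_low = exp(unname(beta - z * se)),
               hr_high = exp(unname(beta + z * se)),
               p_value = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(covariate = character(0), log_hr = numeric(0),
               robust_se = numeric(0), hr = numeric(0), hr_low = numeric(0),
               hr_high = numeric(0), p_value = numeric(0))
  }
  structure(list(shape = unname(exp(theta[1L])),
                 scale = unname(exp(theta[2L])),
                 coefficients = beta, theta = theta, vcov = vc,
                 vcov_model = bread, hr_table = hr_table,
                 loglik = -opt$value, n = length(t), n_event = sum(e),
                 n_clusters = G, conf_level = conf_level),
            class = "weibull_ph")
}

#' @export
print.weibull_ph <- function(x, ...) {
  cat(sprintf("<weibull_ph> shape %.3f, scale %.2f days (n = %d, events = %d, clusters = %d)\n",
              x$shape, x$scale, x$n, x$n_event, x$n_clusters))
  if (nrow(x$hr_table)) {
    print(x$hr_table, row.names = FALSE, digits = 4)
  } else {
    cat("  intercept-only fit\n")
  }
  invisible(x)
}

#' @export
summary.weibull_ph <- function(object, ...) {
  med <- object$scale * log(2)^(1 / object$shape)
  out <- list(fit = object, baseline_median = med)
  class(out) <- "summary.weibull_ph"
  out
}

#' @export
print.summary.weibull_ph <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  baseline median (at covariates = 0): %.2f days\n",
              x$baseline_median))
  invisible(x)
}

#' @export
coef.weibull_ph <- function(object, ...) object$coefficients

#' @export
vcov.weibull_ph <- function(object, ...) object$vcov

#' @export
logLik.weibull_ph <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' @export
confint.weibull_ph <- function(object, parm, level = 0.95, ...) {
  beta <- object$coefficients
  if (!length(beta)) return(matrix(numeric(0), 0, 2))
  se <- sqrt(diag(object$vcov)[-(1:2)])
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(beta - z * se, beta + z * se)
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
#' @rdname weibull_ph_fit
#' @param object A fitted `weibull_ph`.
#' @param newdata data.frame of covariates.
#' @param type `"lp"` (linear predictor), `"hr"` (hazard ratio vs baseline)
#'   or `"median"` (median survival time at the covariates).
#' @param ... Unused.
predict.weibull_ph <- function(object, newdata = NULL,
                               type = c("lp", "hr", "median"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata) || !length(object$coefficients)) 0 else {
    X <- as.matrix(as.data.frame(newdata)[, names(object$coefficients),
                                          drop = FALSE])
    drop(X %*% object$coefficients)
  }
  switch(type,
         lp = eta,
         hr = exp(eta),
         median = object$scale * (log(2) * exp(-eta))^(1 / object$shape))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided test that two samples come from the same distribution. For
#' combined sample sizes up to `exact_max` the permutation null is
#' enumerated exactly (ties handled through midranks); larger samples use
#' the normal approximation with the tie-corrected variance.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest combined size for which the exact branch runs.
#' @return List with `U` (Mann-Whitney statistic for `x`), `p_value`, and
#'   `method` ("exact enumeration" or "normal approximation").
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
rank_sum_test <- function(x, y, exact_max = 20) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (n <= exact_max) {
    combos <- utils::combn(n, nx)
    rs <- colSums(matrix(r[combos], nrow = nx))
    Us <- rs - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    list(U = U, p_value = p, method = "exact enumeration")
  } else {
    tie <- table(r)
    sig2 <- nx * ny / 12 * (n + 1 - sum(tie^3 - tie) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sig2)
    list(U = U, p_value = 2 * stats::pnorm(-abs(z)),
         method = "normal approximation")
  }
}

#' Temperature summaries for one storage site
#'
#' Mean, SD, minimum, maximum, mean of the daily maxima, and mean kinetic
#' temperature of a site's logger series — the summary measures compared
#' across storage-site characteristics.
#'
#' @param series A [temperature_series()].
#' @param delta_h_over_r Activation constant for the MKT, kelvin.
#' @return One-row data.frame with columns `mean_C`, `sd_C`, `min_C`,
#'   `max_C`, `daily_max_mean_C`, `mkt_C`.
#' @export
summarize_site_temps <- function(series, delta_h_over_r = 1e4) {
  stopifnot(inherits(series, "temperature_series"))
  dm <- daily_minmax(series)
  data.frame(mean_C = mean(series$temps),
             sd_C = if (length(series$temps) > 1L) stats::sd(series$temps) else 0,
             min_C = min(series$temps), max_C = max(series$temps),
             daily_max_mean_C = mean(dm$max_C),
             mkt_C = mkt(series, delta_h_over_r = delta_h_over_r))
}

#' Difference in mean temperature summaries between two phases
#'
#' Difference of means with a normal-theory (Welch) 95% confidence interval.
#' With single values on either side the difference is returned with an
#' undefined (NA) interval.
#'
#' @param x,y Numeric vectors of summary values (e.g. per-device daily
#'   maxima or per-site means) for the two phases.
#' @param conf_level Confidence level.
#' @return List with `difference`, `ci` (length-2), `conf_level`.
#' @examples
#' compare_phase_difference(32.8, 28.9)$difference  # 3.9
#' @export
compare_phase_difference <- function(x, y, conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  diff <- mean(x) - mean(y)
  if (length(x) > 1L && length(y) > 1L) {
    se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- c(diff - z * se, diff + z * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(difference = diff, ci = ci, conf_level = conf_level)
}
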