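# Arrhenius lifetime model of the temperature-time indicator, cumulative
# heat-dose integration, and mean kinetic temperature.
#
# The indicator's lifetime at absolute temperature T follows
#   L(T) = L_ref * exp(Ea/R * (1/T - 1/T_ref)),
# so log-lifetime is linear in 1/T with slope Ea/R (the activation ratio,
# in kelvin). Cumulative heat dose over an exposure history is
#   D(t) = D0 + integral dt' / L(T(t')),
# dimensionless, with the discard point at D = 1.

#' Design calibration points of the study's TTI
#'
#' The indicator used on the oxytocin devices is specified to reach its
#' discard point after the equivalent of 17.2 days at 40 degrees C, 72.5 days
#' at 30 degrees C, or 154 days at 25 degrees C.
#'
#' @format A data.frame with columns `temp_C` and `lifetime_days`.
#' @export
tti_design_points <- data.frame(
  temp_C = c(40, 30, 25),
  lifetime_days = c(17.2, 72.5, 154)
)

#' Fit an Arrhenius lifetime model to calibration points
#'
#' Least-squares fit of log-lifetime against inverse absolute temperature.
#' With exactly two points the fit interpolates them exactly. The reference
#' temperature of the returned calibration is the warmest calibration point.
#'
#' @param points data.frame with columns `temp_C` and `lifetime_days`
#'   (at least two distinct temperatures, positive lifetimes).
#' @return A `tti_calibration` object with fields `ref_temp_K`,
#'   `ref_lifetime_days`, `activation_ratio_K` and the fit residuals.
#' @examples
#' fit_arrhenius(tti_design_points)
#' @export
fit_arrhenius <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("temp_C", "lifetime_days") %in% names(points)))
  tC <- as.numeric(points$temp_C)
  lt <- as.numeric(points$lifetime_days)
  if (length(tC) < 2L) stopf("need at least two calibration points")
  if (any(!is.finite(lt)) || any(lt <= 0)) stopf("lifetimes must be positive")
  dup <- duplicated(tC)
  if (any(dup)) {
    for (temp in unique(tC[dup])) {
      if (length(unique(lt[tC == temp])) > 1L) {
        stopf("conflicting lifetimes at %.6g C", temp)
      }
    }
    keep <- !duplicated(tC)
    tC <- tC[keep]; lt <- lt[keep]
    if (length(tC) < 2L) {
      stopf("need at least two distinct calibration temperatures")
    }
  }
  invT <- 1 / celsius_to_kelvin(tC)
  fit <- stats::lm.fit(cbind(1, invT), log(lt))
  ratio <- unname(fit$coefficients[2L])
  if (!is.finite(ratio) || ratio <= 0) {
    stopf("calibration points do not define a positive activation ratio")
  }
  iref <- which.max(tC)
  calib <- structure(
    list(ref_temp_K = celsius_to_kelvin(tC[iref]),
         ref_lifetime_days = unname(exp(fit$coefficients[1L] +
                                          ratio * invT[iref])),
         activation_ratio_K = ratio,
         points = data.frame(temp_C = tC, lifetime_days = lt)),
    class = "tti_calibration"
  )
  calib$points$fitted_days <- lifetime_at(calib, tC)
  calib
}

#' Construct a TTI calibration directly
#'
#' @param ref_temp_C Reference temperature in degrees C.
#' @param ref_lifetime_days Indicator lifetime at the reference temperature.
#' @param activation_ratio_K Activation energy over the gas constant (Ea/R),
#'   in kelvin.
#' @return A `tti_calibration` object.
#' @export
tti_calibration <- function(ref_temp_C, ref_lifetime_days, activation_ratio_K) {
  stopifnot(is.finite(ref_lifetime_days), ref_lifetime_days > 0,
            is.finite(activation_ratio_K), activation_ratio_K > 0,
            ref_temp_C > -KELVIN0)
  structure(list(ref_temp_K = celsius_to_kelvin(ref_temp_C),
                 ref_lifetime_days = ref_lifetime_days,
                 activation_ratio_K = activation_ratio_K,
                 points = NULL),
            class = "tti_calibration")
}

#' The package's default TTI calibration
#'
#' Arrhenius fit to the indicator's three design points
#' ([tti_design_points]); used throughout the synthetic trial generator.
#'
#' @return A `tti_calibration`.
#' @export
default_tti_calibration <- function() fit_arrhenius(tti_design_points)

#' @export
print.tti_calibration <- function(x, ...) {
  cat(sprintf("<tti_calibration> lifetime %.4g days at %.1f C, Ea/R = %.4g K\n",
              x$ref_lifetime_days, kelvin_to_celsius(x$ref_temp_K),
              x$activation_ratio_K))
  if (!is.null(x$points)) {
    cat("  fit to calibration points:\n")
    print(x$points, row.names = FALSE)
  }
  invisible(x)
}

#' Predicted indicator lifetime at given temperatures
#'
#' @param calib A `tti_calibration`.
#' @param temp_C Temperatures in degrees C (vectorised).
#' @return Lifetimes in days.
#' @examples
#' lifetime_at(default_tti_calibration(), 30)
#' @export
lifetime_at <- function(calib, temp_C) {
  stopifnot(inherits(calib, "tti_calibration"))
  if (any(temp_C <= -KELVIN0)) stopf("temperature below absolute zero")
  TK <- celsius_to_kelvin(temp_C)
  unname(calib$ref_lifetime_days *
           exp(calib$activation_ratio_K * (1 / TK - 1 / calib$ref_temp_K)))
}

#' @export
#' @rdname lifetime_at
#' @param object A `tti_calibration`.
#' @param newdata Optional data.frame with a `temp_C` column (or numeric
#'   vector of temperatures).
#' @param ... Unused.
predict.tti_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(lifetime_at(object, object$points$temp_C))
  t <- if (is.data.frame(newdata)) newdata$temp_C else as.numeric(newdata)
  lifetime_at(object, t)
}

#' Accumulate heat dose over a temperature series
#'
#' Integrates the fraction of indicator life consumed, treating the
#' temperature as piecewise-constant over each logging interval: each
#' reading contributes `interval / lifetime_at(temp)`. The discard time is
#' the first time the cumulative dose reaches 1 (located by linear
#' interpolation within the crossing interval).
#'
#' @param calib A `tti_calibration`.
#' @param series A [temperature_series()].
#' @param initial_dose Dose already accumulated before the series starts
#'   (fraction in \[0, 1)).
#' @return A `dose_trajectory`: list with `times` (POSIXct, end of each
#'   interval), `dose` (cumulative fraction), `discard_time` (POSIXct or NA),
#'   `discard_days` (days from series start, or NA).
#' @examples
#' calib <- default_tti_calibration()
#' s <- temperature_series(rep(40, 48 * 20), "2011-07-25 06:00:00", 30)
#' accumulate_dose(calib, s)$discard_days  # ~17.2
#' @export
accumulate_dose <- function(calib, series, initial_dose = 0) {
  stopifnot(inherits(calib, "tti_calibration"),
            inherits(series, "temperature_series"))
  if (!length(series$temps)) stopf("empty temperature series")
  if (initial_dose < 0 || initial_dose >= 1) {
    stopf("`initial_dose` must be in [0, 1)")
  }
  dt_days <- series$interval_min / 1440
  inc <- dt_days / lifetime_at(calib, series$temps)
  dose <- initial_dose + cumsum(inc)
  hit <- which(dose >= 1)
  if (length(hit)) {
    i <- hit[1L]
    before <- if (i == 1L) initial_dose else dose[i - 1L]
    frac <- (1 - before) / inc[i]
    discard_days <- (i - 1L + frac) * dt_days
    discard_time <- series$start + discard_days * 86400
  } else {
    discard_days <- NA_real_
    discard_time <- as.POSIXct(NA)
  }
  structure(list(times = series_times(series) + series$interval_min * 60,
                 dose = dose, initial_dose = initial_dose,
                 discard_time = discard_time, discard_days = discard_days),
            class = "dose_trajectory")
}

#' @export
print.dose_trajectory <- function(x, ...) {
  cat(sprintf("<dose_trajectory> %d steps, dose %.3f -> %.3f\n",
              length(x$dose), x$initial_dose, x$dose[length(x$dose)]))
  if (is.na(x$discard_days)) {
    cat("  discard threshold not reached\n")
  } else {
    cat(sprintf("  discard threshold crossed %.2f days after start\n",
                x$discard_days))
  }
  invisible(x)
}

#' @export
plot.dose_trajectory <- function(x, ...) {
  graphics::plot(x$times, x$dose, type = "l", xlab = "time",
                 ylab = "cumulative dose (fraction of indicator life)", ...)
  graphics::abline(h = 1, lty = 2)
  if (!is.na(x$discard_days)) graphics::abline(v = x$discard_time, lty = 3)
  invisible(x)
}

#' Mean kinetic temperature of a series of readings
#'
#' The single temperature that, held constant, produces the same
#' Arrhenius-weighted degradation as the fluctuating readings:
#' `MKT = (dH/R) / (-log(mean(exp(-dH/(R * T_i)))))`, in kelvin, reported in
#' degrees C. The default activation constant is the ICH stability
#' convention, dH/R = 10000 K (dH = 83.144 kJ/mol).
#'
#' @param x A [temperature_series()] or a numeric vector of readings in
#'   degrees C.
#' @param delta_h_over_r Activation constant dH/R in kelvin.
#' @return MKT in degrees C.
#' @examples
#' mkt(c(20, 40))  # 34.36, well above the arithmetic mean of 30
#' @export
mkt <- function(x, delta_h_over_r = 1e4) {
  temps <- if (inherits(x, "temperature_series")) x$temps else as.numeric(x)
  if (!length(temps)) stopf("empty temperature series")
  TK <- celsius_to_kelvin(temps)
  # log-sum-exp for numerical stability of mean(exp(-k/T))
  z <- -delta_h_over_r / TK
  m <- max(z)
  lmean <- m + log(mean(exp(z - m)))
  kelvin_to_celsius(-delta_h_over_r / lmean)
}

#' Mean kinetic temperature from daily minimum/maximum pairs
#'
#' Applies the MKT formula to the pooled daily extremes (two readings per
#' day), the summary available when only a min/max thermometer record
#' exists.
#'
#' @param days data.frame with columns `min_C` and `max_C`, one row per day.
#' @param delta_h_over_r Activation constant dH/R in kelvin.
#' @return MKT in degrees C.
#' @export
mkt_from_daily_minmax <- function(days, delta_h_over_r = 1e4) {
  stopifnot(is.data.frame(days), all(c("min_C", "max_C") %in% names(days)))
  if (!nrow(days)) stopf("no daily records")
  if (any(days$min_C > days$max_C)) {
    i <- which(days$min_C > days$max_C)[1L]
    stopf("daily min exceeds max at row %d", i,
          class = "heatdose_validation_error")
  }
  mkt(c(days$min_C, days$max_C), delta_h_over_r = delta_h_over_r)
}

#' Read or write a TTI calibration as YAML
#'
#' Stored as `{ref_temp_C, ref_lifetime_days, activation_ratio_K}`.
#'
#' @param path YAML file path.
#' @return `read_calibration_yaml` returns a `tti_calibration`;
#'   `write_calibration_yaml` returns `path` invisibly.
#' @export
read_calibration_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  tti_calibration(y$ref_temp_C, y$ref_lifetime_days, y$activation_ratio_K)
}

#' @rdname read_calibration_yaml
#' @param calib A `tti_calibration`.
#' @export
write_calibration_yaml <- function(calib, path) {
  stopifnot(inherits(calib, "tti_calibration"))
  yaml::write_yaml(list(ref_temp_C = kelvin_to_celsius(calib$ref_temp_K),
                        ref_lifetime_days = calib$ref_lifetime_days,
                        activation_ratio_K = calib$activation_ratio_K),
                   path)
  invisible(path)
}
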