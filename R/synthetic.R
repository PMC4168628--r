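# Synthetic-data generators: diurnal ambient temperature series, multi-stage
# refrigerated-shipment profiles, and complete simulated field-storage trials
# (sites, loggers, daily TTI calendars). Defaults emulate the two seasons of
# the Ghana field study; see the methods vignette for the calibration.

#' Climate preset for one study phase
#'
#' Parameters of the diurnal indoor-temperature generator. The shipped
#' presets (phases 1 and 2) are calibrated so that synthetic trials
#' reproduce the reported study conditions: mean daily maxima near 28.9 and
#' 32.8 degrees C and site-level mean kinetic temperatures spanning roughly
#' 25.1-28.5 and 27.6-33.0 degrees C respectively.
#'
#' @param phase 1 (rainy-season round) or 2 (dry/harmattan round) to load a
#'   shipped preset, or NULL to build one from the remaining arguments.
#' @param daily_mean Site-average daily mean temperature, degrees C.
#' @param diurnal_amplitude Half-range of the diurnal cycle, degrees C.
#' @param site_spread_sd SD of the additive between-site offset, degrees C.
#' @param noise_sd Stationary SD of the AR(1) reading noise, degrees C.
#' @param noise_autocorr Lag-one autocorrelation of the reading noise
#'   (per reading, at the preset's logging interval).
#' @param interval_min Logging interval of the phase's loggers, minutes.
#' @param initial_dose_mean,initial_dose_sd Mean and SD of the indicator
#'   dose already accumulated when devices reach the field workers
#'   (calibrated so phase median discard times match the observed 43 and
#'   33 days).
#' @param no_ceiling_sd_mult Multiplier on `noise_sd` for storage sites
#'   without a ceiling (absence of a ceiling increases temperature
#'   variability, not its mean).
#' @param start_date First field day of the phase.
#' @return An object of class `climate_preset`.
#' @export
climate_preset <- function(phase = NULL, daily_mean = 26.5,
                           diurnal_amplitude = 2.4, site_spread_sd = 0.8,
                           noise_sd = 0.5, noise_autocorr = 0.9,
                           interval_min = 10, initial_dose_mean = 0.6,
                           initial_dose_sd = 0.05, no_ceiling_sd_mult = 1.5,
                           start_date = "2011-07-25") {
  if (!is.null(phase)) {
    path <- system.file("extdata", "presets",
                        sprintf("climate_phase%d.yaml", as.integer(phase)),
                        package = "heatdose", mustWork = TRUE)
    y <- yaml::read_yaml(path)
    return(do.call(climate_preset,
                   c(list(phase = NULL), y[setdiff(names(y), "phase")])))
  }
  if (diurnal_amplitude < 0) stopf("diurnal amplitude must be >= 0")
  if (site_spread_sd < 0 || noise_sd < 0) stopf("spread/noise SDs must be >= 0")
  if (noise_autocorr < 0 || noise_autocorr >= 1) {
    stopf("noise autocorrelation must be in [0, 1)")
  }
  structure(list(daily_mean = daily_mean,
                 diurnal_amplitude = diurnal_amplitude,
                 site_spread_sd = site_spread_sd, noise_sd = noise_sd,
                 noise_autocorr = noise_autocorr,
                 interval_min = as.integer(interval_min),
                 initial_dose_mean = initial_dose_mean,
                 initial_dose_sd = initial_dose_sd,
                 no_ceiling_sd_mult = no_ceiling_sd_mult,
                 start_date = as.Date(start_date)),
            class = "climate_preset")
}

#' @export
print.climate_preset <- function(x, ...) {
  cat(sprintf(paste0("<climate_preset> mean %.1f C, amplitude %.1f C, ",
                     "site spread %.1f C, noise %.2f C (ar %.2f)\n"),
              x$daily_mean, x$diurnal_amplitude, x$site_spread_sd,
              x$noise_sd, x$noise_autocorr))
  invisible(x)
}

# Deterministic diurnal shape: minimum at 06:00, maximum at 15:00, joined by
# half-cosine arcs (a 9 h rise, a 15 h fall). Each arc averages to zero, so
# the daily mean equals `daily_mean`. `hours` is time of day in [0, 24).
diurnal_shape <- function(hours) {
  h <- hours %% 24
  rise <- h >= 6 & h < 15
  out <- numeric(length(h))
  out[rise] <- -cos(pi * (h[rise] - 6) / 9)
  hf <- (h[!rise] - 15) %% 24
  out[!rise] <- cos(pi * hf / 15)
  out
}

#' Generate a diurnal indoor temperature series
#'
#' Deterministic diurnal cycle (minimum 06:00, maximum 15:00) around
#' `daily_mean + site_offset`, plus stationary AR(1) reading noise.
#' Reproducible under a fixed seed.
#'
#' @param preset A [climate_preset()].
#' @param site_offset Additive site-level offset in degrees C.
#' @param days Number of days to generate (>= 1).
#' @param interval_min Logging interval in minutes (defaults to the preset's).
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @param logger_id Label for the synthetic logger.
#' @param noise_mult Multiplier on the preset's noise SD (used for
#'   no-ceiling sites).
#' @return A [temperature_series()] starting at midnight of the preset's
#'   start date.
#' @export
gen_diurnal_series <- function(preset, site_offset = 0, days = 60,
                               interval_min = preset$interval_min,
                               seed = NULL, logger_id = "synthetic",
                               noise_mult = 1) {
  stopifnot(inherits(preset, "climate_preset"))
  if (days < 1) stopf("`days` must be >= 1")
  n <- as.integer(round(days * 1440 / interval_min))
  hours <- (seq_len(n) - 1L) * interval_min / 60
  base <- preset$daily_mean + site_offset +
    preset$diurnal_amplitude * diurnal_shape(hours)
  sd_noise <- preset$noise_sd * noise_mult
  noise <- if (sd_noise > 0) {
    with_seed(seed, {
      phi <- preset$noise_autocorr
      innov <- stats::rnorm(n, sd = sd_noise * sqrt(1 - phi^2))
      innov[1L] <- stats::rnorm(1L, sd = sd_noise)
      as.numeric(stats::filter(innov, phi, method = "recursive"))
    })
  } else 0
  temps <- pmin(pmax(base + noise, -40), 70)
  temperature_series(temps,
                     start = as.POSIXct(paste(preset$start_date, "00:00:00"),
                                        tz = "UTC"),
                     interval_min = interval_min, logger_id = logger_id)
}

#' Shipment stages and profiles
#'
#' A shipment profile is a sequence of stages (refrigerated air legs, a
#' non-climate-controlled customs hold, road transport), each held at a
#' stage temperature with white measurement/handling noise. The shipped
#' presets reproduce the two monitored factory-to-storage shipments: batch 1
#' with a mean kinetic temperature near 10.3 degrees C over 8.6 days and
#' batch 2 near 12.1 degrees C over 13.4 days.
#'
#' @param batch 1 or 2 to load a shipped six-stage preset.
#' @return A data.frame of stages with columns `name`, `duration_days`,
#'   `temp_C`, `temp_sd`.
#' @export
shipment_stages <- function(batch = 1) {
  path <- system.file("extdata", "presets",
                      sprintf("shipment_batch%d.yaml", as.integer(batch)),
                      package = "heatdose", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  do.call(rbind, lapply(y$stages, as.data.frame))
}

#' @rdname shipment_stages
#' @param stages data.frame as returned by [shipment_stages()] (columns
#'   `name`, `duration_days`, `temp_C`, `temp_sd`).
#' @param interval_min Logging interval in minutes.
#' @param seed Integer seed, or NULL.
#' @param start Start timestamp of the shipment.
#' @param logger_id Label for the synthetic logger.
#' @return `gen_shipment_profile` returns a [temperature_series()] covering
#'   the concatenated stages.
#' @export
gen_shipment_profile <- function(stages, interval_min = 30, seed = NULL,
                                 start = "2010-08-01 00:00:00",
                                 logger_id = "shipment") {
  stopifnot(is.data.frame(stages), nrow(stages) >= 1,
            all(c("duration_days", "temp_C", "temp_sd") %in% names(stages)))
  if (any(stages$duration_days <= 0)) stopf("stage durations must be positive")
  temps <- with_seed(seed, {
    unlist(lapply(seq_len(nrow(stages)), function(i) {
      n <- max(1L, as.integer(round(stages$duration_days[i] * 1440 /
                                      interval_min)))
      stages$temp_C[i] + stats::rnorm(n, sd = stages$temp_sd[i])
    }))
  })
  temperature_series(pmin(pmax(temps, -40), 70),
                     start = as.POSIXct(start, tz = "UTC"),
                     interval_min = interval_min, logger_id = logger_id)
}

#' Configuration of a synthetic field-storage trial
#'
#' @param phase Study phase (1 or 2); selects the climate preset and start
#'   date unless overridden.
#' @param n_sites Number of storage sites (field workers).
#' @param devices_per_site Devices issued to each site.
#' @param climate A [climate_preset()].
#' @param calib A `tti_calibration` for the indicator's dose model.
#' @param seed Integer seed driving the whole trial.
#' @param max_days Observation cap in days; devices not discarded by then
#'   are right-censored.
#' @param status3_lag Days after the discard point at which the indicator is
#'   recorded as status 3 (cosmetic; the analysis keys on first status >= 2).
#' @param n_no_ceiling Number of sites without a ceiling (13 of 23 in the
#'   study); these get inflated temperature variability.
#' @param site_covariate_effects Optional named numeric vector of
#'   log-acceleration factors applied to the dose-accumulation rate per unit
#'   of a site covariate (names among `ceiling`, `fan`, `cooking_in_room`,
#'   `district_north`).
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(phase = 1, n_sites = 23, devices_per_site = 25,
                         climate = climate_preset(phase),
                         calib = default_tti_calibration(), seed = 1,
                         max_days = 120, status3_lag = 7,
                         n_no_ceiling = 13, site_covariate_effects = NULL) {
  stopifnot(n_sites > 0, devices_per_site > 0, max_days >= 1)
  structure(list(phase = as.integer(phase), n_sites = as.integer(n_sites),
                 devices_per_site = as.integer(devices_per_site),
                 climate = climate, calib = calib, seed = seed,
                 max_days = as.integer(max_days),
                 status3_lag = as.integer(status3_lag),
                 n_no_ceiling = min(as.integer(n_no_ceiling),
                                    as.integer(n_sites)),
                 site_covariate_effects = site_covariate_effects),
            class = "trial_config")
}

#' Generate a complete synthetic field-storage trial
#'
#' Draws site characteristics and site-level temperature offsets, generates
#' one logger series per site, runs every device through the indicator's
#' heat-dose model (with a device-specific initial dose reflecting
#' pre-issue exposure and indicator variability), and renders each device's
#' history as a daily status calendar observed each morning.
#'
#' @param config A [trial_config()].
#' @return A list of class `synthetic_trial` with elements `sites`
#'   (data.frame of site characteristics), `series` (named list of
#'   [temperature_series()], one per site), `calendars` (list of
#'   [tti_calendar()], one per device) and `config`.
#' @examples
#' \donttest{
#' trial <- gen_trial(trial_config(phase = 1, seed = 42))
#' recs <- trial_records(trial)
#' km_estimate(recs)
#' }
#' @export
gen_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  cl <- config$climate
  with_seed(config$seed, {
    ns <- config$n_sites
    site_id <- sprintf("S%02d", seq_len(ns))
    ceiling <- rep(TRUE, ns)
    ceiling[sample.int(ns, config$n_no_ceiling)] <- FALSE
    sites <- data.frame(
      site_id = site_id,
      district = sample(c("North", "South"), ns, replace = TRUE),
      ceiling = ceiling,
      roof_material = sample(c("metal", "thatch"), ns, replace = TRUE,
                             prob = c(0.8, 0.2)),
      wall_material = sample(c("mud", "cement"), ns, replace = TRUE),
      fan = sample(c(TRUE, FALSE), ns, replace = TRUE, prob = c(0.3, 0.7)),
      cooking_in_room = sample(c(TRUE, FALSE), ns, replace = TRUE,
                               prob = c(0.2, 0.8)),
      stringsAsFactors = FALSE
    )
    offsets <- stats::rnorm(ns, sd = cl$site_spread_sd)
    # district effect is folded into the offset ordering: northern sites run
    # warmer, as observed in the field
    offsets <- offsets + ifelse(sites$district == "North", 0.3, -0.3)
    series_seeds <- stream_seed(config$seed, seq_len(ns))
    dose_seeds <- stream_seed(config$seed, ns + seq_len(ns))
    t0 <- cl$start_date
    series <- vector("list", ns)
    calendars <- list()
    rate_mult <- rep(1, ns)
    if (!is.null(config$site_covariate_effects)) {
      eff <- config$site_covariate_effects
      X <- cbind(ceiling = as.numeric(sites$ceiling),
                 fan = as.numeric(sites$fan),
                 cooking_in_room = as.numeric(sites$cooking_in_room),
                 district_north = as.numeric(sites$district == "North"))
      use <- intersect(names(eff), colnames(X))
      if (length(use)) {
        rate_mult <- exp(as.numeric(X[, use, drop = FALSE] %*% eff[use]))
      }
    }
    for (i in seq_len(ns)) {
      s <- gen_diurnal_series(
        cl, site_offset = offsets[i], days = config$max_days,
        seed = series_seeds[i], logger_id = paste0("LT-", site_id[i]),
        noise_mult = if (sites$ceiling[i]) 1 else cl$no_ceiling_sd_mult
      )
      series[[i]] <- s
      traj <- accumulate_dose(config$calib, s, initial_dose = 0)
      cumdose <- traj$dose * rate_mult[i]
      dt_days <- s$interval_min / 1440
      doses0 <- with_seed(dose_seeds[i], {
        pmin(pmax(stats::rnorm(config$devices_per_site,
                               mean = cl$initial_dose_mean,
                               sd = cl$initial_dose_sd), 0), 0.95)
      })
      for (j in seq_len(config$devices_per_site)) {
        target <- 1 - doses0[j]
        idx <- findInterval(target, cumdose) + 1L
        if (idx > length(cumdose)) {
          disc_day <- NA_integer_
        } else {
          prev <- if (idx == 1L) 0 else cumdose[idx - 1L]
          frac <- (target - prev) / (cumdose[idx] - prev)
          disc_day <- as.integer(ceiling((idx - 1L + frac) * dt_days + 1e-12))
          disc_day <- max(disc_day, 1L)
        }
        last_day <- if (is.na(disc_day)) config$max_days else {
          min(config$max_days, disc_day + config$status3_lag + 3L)
        }
        st <- rep(1L, last_day)
        if (!is.na(disc_day) && disc_day <= last_day) {
          st[seq(disc_day, last_day)] <- 2L
          d3 <- disc_day + config$status3_lag
          if (d3 <= last_day) st[seq(d3, last_day)] <- 3L
        }
        calendars[[length(calendars) + 1L]] <-
          tti_calendar(sprintf("%s-D%02d", site_id[i], j), site_id[i],
                       dates = t0 + seq_len(last_day), statuses = st)
      }
    }
    names(series) <- site_id
    structure(list(sites = sites, series = series, calendars = calendars,
                   config = config),
              class = "synthetic_trial")
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> phase %d: %d sites x %d devices (%d calendars)\n",
              x$config$phase, x$config$n_sites, x$config$devices_per_site,
              length(x$calendars)))
  invisible(x)
}

#' Discard records of a synthetic trial
#'
#' Validates every device calendar of a [gen_trial()] result into the
#' analyzable one-row-per-device record table.
#'
#' @param trial A `synthetic_trial`.
#' @return data.frame of discard records.
#' @export
trial_records <- function(trial) {
  stopifnot(inherits(trial, "synthetic_trial"))
  out <- do.call(rbind, lapply(trial$calendars, validate_calendar,
                               phase = trial$config$phase))
  rownames(out) <- NULL
  out
}

#' Reconstruct a Weibull discard distribution from two printed summaries
#'
#' Solves for the unique Weibull(shape, scale) with median `median` and
#' cumulative discard fraction `anchor_F` at time `anchor_t` — the two
#' quantile equations have the closed-form solution
#' `shape = log(log(1 - F) / log(0.5)) / log(t / m)`,
#' `scale = m / log(2)^(1/shape)`. Used to rebuild each study phase's
#' discard-time distribution from its reported median and 30-day discard
#' proportion for the wastage simulator.
#'
#' @param median Distribution median in days.
#' @param anchor_t Second time point in days.
#' @param anchor_F Cumulative discard fraction at `anchor_t` (in (0, 1)).
#' @return Named numeric vector `c(shape, scale)`.
#' @examples
#' weibull_from_summaries(43, 30, 88 / 550)   # phase 1
#' weibull_from_summaries(33, 30, 196 / 575)  # phase 2
#' @export
weibull_from_summaries <- function(median, anchor_t, anchor_F) {
  stopifnot(median > 0, anchor_t > 0)
  if (anchor_F <= 0 || anchor_F >= 1) stopf("`anchor_F` must be in (0, 1)")
  if (anchor_t == median) {
    stopf(if (anchor_F == 0.5) {
      "degenerate constraints: the anchor repeats the median"
    } else {
      "inconsistent constraints: F(median) must be 0.5"
    })
  }
  shape <- log(log1p(-anchor_F) / log(0.5)) / log(anchor_t / median)
  if (!is.finite(shape) || shape <= 0) {
    stopf("no positive-shape Weibull satisfies these constraints")
  }
  scale <- median / log(2)^(1 / shape)
  c(shape = shape, scale = scale)
}
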