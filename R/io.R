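# File formats: logger CSV, TTI status calendars, site tables.
#
# All files are UTF-8 comma-separated with ISO-8601 dates/timestamps.
# Logger CSV columns:   logger_id, timestamp, temp_C (uniform spacing)
# Calendar CSV columns: device_id, site_id, date, status (status in 1/2/3)
# Site CSV columns:     site_id, district, ceiling, roof_material,
#                       wall_material, fan, cooking_in_room

#' Read a temperature-logger CSV
#'
#' Expects columns `logger_id`, `timestamp` (ISO-8601), `temp_C`, one reading
#' per row, uniformly spaced. The recording interval is inferred from the
#' first two rows and every subsequent row is checked against it.
#'
#' @param path Path to the CSV file.
#' @return A [temperature_series()].
#' @export
read_logger_csv <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("logger_id", "timestamp", "temp_C")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("logger CSV %s is missing column(s): %s", path,
          paste(miss, collapse = ", "), class = "heatdose_format_error")
  }
  if (nrow(df) < 1L) stopf("logger CSV %s has no readings", path)
  ts <- parse_timestamp(df$timestamp)
  if (anyNA(ts)) {
    stopf("malformed timestamp '%s' at row %d of %s",
          df$timestamp[which(is.na(ts))[1L]], which(is.na(ts))[1L], path,
          class = "heatdose_format_error")
  }
  if (nrow(df) == 1L) {
    return(temperature_series(df$temp_C, start = ts[1L], interval_min = 1L,
                              logger_id = df$logger_id[1L]))
  }
  steps <- as.numeric(difftime(ts[-1L], ts[-length(ts)], units = "mins"))
  interval <- steps[1L]
  if (!isTRUE(interval > 0)) {
    stopf("non-positive recording interval between rows 1 and 2 of %s", path,
          class = "heatdose_format_error")
  }
  off <- which(abs(steps - interval) > 1e-6)
  if (length(off)) {
    stopf("non-uniform spacing at row %d of %s (%.3g min, expected %.3g)",
          off[1L] + 1L, path, steps[off[1L]], interval,
          class = "heatdose_format_error")
  }
  temperature_series(df$temp_C, start = ts[1L], interval_min = interval,
                     logger_id = df$logger_id[1L])
}

#' Write a temperature series as logger CSV
#'
#' Readings are written with enough digits that a write/read round trip
#' reproduces the values bit-for-bit.
#'
#' @param series A [temperature_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(series, path) {
  df <- data.frame(
    logger_id = series$logger_id,
    timestamp = format(series_times(series), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    temp_C = sprintf("%.17g", series$temps),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Daily TTI status calendar for one device
#'
#' One record of the three-level indicator status ("1" inner square lighter
#' than the outer circle, "2" same colour = discard point, "3" darker) per
#' consecutive calendar day, as recorded by a field worker each morning.
#'
#' @param device_id,site_id Character labels.
#' @param dates Consecutive increasing `Date`s (or ISO-8601 strings).
#' @param statuses Integer codes in `{1, 2, 3}`, one per date.
#' @return An object of class `tti_calendar`.
#' @export
tti_calendar <- function(device_id, site_id, dates, statuses) {
  dates <- as.Date(dates)
  statuses <- as.integer(statuses)
  if (length(dates) != length(statuses) || !length(dates)) {
    stopf("dates and statuses must be non-empty and equal length")
  }
  if (!all(statuses %in% 1:3)) {
    stopf("device %s: status codes must be 1, 2 or 3", device_id,
          class = "heatdose_validation_error")
  }
  if (length(dates) > 1L) {
    dd <- as.integer(diff(dates))
    gap <- which(dd != 1L)
    if (length(gap)) {
      stopf("device %s: calendar gap after %s (next record %s)",
            device_id, format(dates[gap[1L]]), format(dates[gap[1L] + 1L]),
            class = "heatdose_gap_error")
    }
  }
  structure(list(device_id = as.character(device_id),
                 site_id = as.character(site_id),
                 dates = dates, statuses = statuses),
            class = "tti_calendar")
}

#' Validate a status calendar into a discard record
#'
#' The receipt date T0 is the day before the first daily check. The discard
#' event is the first day the status reaches 2 or higher (the inner square
#' has caught up with the outer circle); a device never seen at status >= 2
#' is right-censored at its last observed day. A status regression (for
#' example 2 then 1) is a recording error and is rejected rather than
#' repaired, as is any gap in the calendar.
#'
#' @param cal A [tti_calendar()].
#' @param phase Study phase label (1 or 2) carried into the record.
#' @return A one-row data.frame (a discard record) with columns
#'   `device_id`, `site_id`, `phase`, `t0`, `time_days`, `event`.
#' @export
validate_calendar <- function(cal, phase = 1L) {
  stopifnot(inherits(cal, "tti_calendar"))
  s <- cal$statuses
  if (any(diff(s) < 0L)) {
    i <- which(diff(s) < 0L)[1L] + 1L
    stopf("device %s: status regressed from %d to %d on %s",
          cal$device_id, s[i - 1L], s[i], format(cal$dates[i]),
          class = "heatdose_quality_error")
  }
  t0 <- cal$dates[1L] - 1L
  hit <- which(s >= 2L)
  if (length(hit)) {
    time_days <- as.integer(cal$dates[hit[1L]] - t0)
    event <- TRUE
  } else {
    time_days <- as.integer(cal$dates[length(s)] - t0)
    event <- FALSE
  }
  data.frame(device_id = cal$device_id, site_id = cal$site_id,
             phase = as.integer(phase), t0 = t0,
             time_days = time_days, event = event,
             stringsAsFactors = FALSE)
}

#' Read a calendar CSV into discard records
#'
#' The file holds daily status rows for many devices (columns `device_id`,
#' `site_id`, `date`, `status`). Each device's rows are validated with
#' [validate_calendar()]; any device with a gap or a status regression
#' aborts the read with an informative error (invalid devices are rejected,
#' not imputed).
#'
#' @param path CSV path.
#' @param phase Study phase label attached to every record.
#' @return A data.frame of discard records, one row per device.
#' @export
read_calendar_csv <- function(path, phase = 1L) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("device_id", "site_id", "date", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("calendar CSV %s is missing column(s): %s", path,
          paste(miss, collapse = ", "), class = "heatdose_format_error")
  }
  df$date <- as.Date(df$date)
  recs <- lapply(split(df, df$device_id), function(d) {
    d <- d[order(d$date), ]
    validate_calendar(tti_calendar(d$device_id[1L], d$site_id[1L],
                                   d$date, d$status), phase = phase)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Write status calendars to CSV
#'
#' @param calendars List of [tti_calendar()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calendar_csv <- function(calendars, path) {
  rows <- lapply(calendars, function(cal) {
    data.frame(device_id = cal$device_id, site_id = cal$site_id,
               date = format(cal$dates), status = cal$statuses,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a storage-site characteristics table
#'
#' @param path CSV with columns `site_id`, `district` (North/South),
#'   `ceiling`, `roof_material`, `wall_material`, `fan`, `cooking_in_room`.
#' @return A data.frame, one row per site.
#' @export
read_sites_csv <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "district", "ceiling", "roof_material",
            "wall_material", "fan", "cooking_in_room")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("site CSV %s is missing column(s): %s", path,
          paste(miss, collapse = ", "), class = "heatdose_format_error")
  }
  if (anyDuplicated(df$site_id)) {
    stopf("duplicate site_id in %s", path, class = "heatdose_validation_error")
  }
  for (col in c("ceiling", "fan", "cooking_in_room")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Crude proportion of devices discarded by a time point
#'
#' The raw fraction of devices whose discard event occurred on or before
#' day `t` — the "how many would be lost at a 30-day resupply visit"
#' summary. Only valid when no device is censored before `t`; with earlier
#' censoring the Kaplan-Meier estimator ([km_estimate()]) must be used
#' instead.
#'
#' @param records Discard records (data.frame as from [validate_calendar()]),
#'   all from one phase.
#' @param t Time point in days.
#' @return Fraction in \[0, 1\].
#' @examples
#' recs <- data.frame(device_id = as.character(1:5), site_id = "s1",
#'                    phase = 1L, t0 = as.Date("2011-07-25"),
#'                    time_days = c(10, 20, 30, 40, 50), event = TRUE)
#' proportion_discarded_by(recs, 30)  # 3/5
#' @export
proportion_discarded_by <- function(records, t) {
  if (is.null(records) || nrow(records) == 0L) {
    stopf("no discard records supplied")
  }
  if (length(unique(records$phase)) > 1L) {
    stopf("records mix study phases; summarise one phase at a time")
  }
  if (any(!records$event & records$time_days < t)) {
    stopf(paste("some devices are censored before day %g; use km_estimate()",
                "for a censoring-aware estimate"), t)
  }
  mean(records$event & records$time_days <= t)
}
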