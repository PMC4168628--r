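#' Temperature series from a single ambient logger
#'
#' A `temperature_series` holds uniformly spaced temperature readings from
#' one battery-operated logger (a LogTag-style device): a logger id, the
#' timestamp of the first reading, the fixed recording interval in minutes,
#' and the readings in degrees Celsius.
#'
#' @param temps Numeric vector of readings in degrees Celsius. All readings
#'   must be finite and within \[-40, 70\] degrees C, the plausible range for
#'   ambient pharmaceutical-storage monitoring.
#' @param start POSIXct (or ISO-8601 string) timestamp of the first reading.
#' @param interval_min Recording interval in minutes; a positive whole number.
#' @param logger_id Character label for the logger.
#' @return An object of class `temperature_series`.
#' @examples
#' s <- temperature_series(c(20, 21, 22), start = "2011-07-25 06:00:00",
#'                         interval_min = 30, logger_id = "LT-001")
#' series_duration_days(s)
#' @export
temperature_series <- function(temps, start, interval_min, logger_id = "logger") {
  temps <- as.numeric(temps)
  if (length(temps) < 1L) {
    stopf("a temperature series needs at least one reading")
  }
  if (anyNA(temps) || any(!is.finite(temps))) {
    stopf("non-finite temperature reading at row %d",
          which(!is.finite(temps))[1L], class = "heatdose_validation_error")
  }
  bad <- which(temps < -40 | temps > 70)
  if (length(bad)) {
    stopf("temperature %.1f C at row %d outside the plausible range [-40, 70]",
          temps[bad[1L]], bad[1L], class = "heatdose_validation_error")
  }
  if (is.character(start)) {
    start <- parse_timestamp(start)
    if (is.na(start)) stopf("unparseable start timestamp")
  }
  if (!inherits(start, "POSIXct")) stopf("`start` must be POSIXct or ISO-8601 text")
  interval_min <- as.numeric(interval_min)
  if (length(interval_min) != 1L || !is.finite(interval_min) ||
      interval_min <= 0 || interval_min != round(interval_min)) {
    stopf("`interval_min` must be a positive whole number of minutes",
          class = "heatdose_format_error")
  }
  structure(
    list(logger_id = as.character(logger_id), start = start,
         interval_min = as.integer(interval_min), temps = temps),
    class = "temperature_series"
  )
}

parse_timestamp <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], format = fmt, tz = "UTC"))
  }
  out
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("<temperature_series> logger %s: %d readings every %d min from %s\n",
              x$logger_id, length(x$temps), x$interval_min,
              format(x$start, "%Y-%m-%d %H:%M", tz = "UTC")))
  cat(sprintf("  range %.1f to %.1f C over %.2f days\n",
              min(x$temps), max(x$temps), series_duration_days(x)))
  invisible(x)
}

#' Reading timestamps of a temperature series
#'
#' @param series A [temperature_series()].
#' @return POSIXct vector, one timestamp per reading.
#' @export
series_times <- function(series) {
  series$start + (seq_along(series$temps) - 1L) * series$interval_min * 60
}

#' Duration spanned by a temperature series, in days
#'
#' The duration covered by the readings, counting each reading as one
#' interval of exposure (piecewise-constant convention).
#'
#' @param series A [temperature_series()].
#' @return Days as a numeric scalar.
#' @export
series_duration_days <- function(series) {
  length(series$temps) * series$interval_min / 1440
}

#' @export
as.data.frame.temperature_series <- function(x, ...) {
  data.frame(logger_id = x$logger_id,
             timestamp = series_times(x),
             temp_C = x$temps,
             stringsAsFactors = FALSE)
}

#' Concatenate temperature series end-to-end
#'
#' Used to assemble multi-stage exposure profiles (for example the legs of a
#' refrigerated shipment). All pieces must share the recording interval; the
#' result starts at the first piece's start time.
#'
#' @param ... `temperature_series` objects.
#' @return A single `temperature_series`.
#' @export
concat_series <- function(...) {
  pieces <- list(...)
  if (length(pieces) == 1L && is.list(pieces[[1L]]) &&
      !inherits(pieces[[1L]], "temperature_series")) {
    pieces <- pieces[[1L]]
  }
  if (!length(pieces)) stopf("nothing to concatenate")
  iv <- unique(vapply(pieces, function(p) p$interval_min, 1L))
  if (length(iv) != 1L) stopf("all pieces must share one recording interval")
  temperature_series(unlist(lapply(pieces, `[[`, "temps")),
                     start = pieces[[1L]]$start, interval_min = iv,
                     logger_id = pieces[[1L]]$logger_id)
}

#' Daily minimum and maximum temperatures
#'
#' Collapses a logged series to one (min, max) pair per calendar day,
#' mirroring how field workers' ambient exposure was summarised before
#' computing a mean kinetic temperature from daily extremes.
#'
#' @param series A [temperature_series()].
#' @return A data.frame with columns `date`, `min_C`, `max_C`.
#' @export
daily_minmax <- function(series) {
  d <- as.Date(format(series_times(series), "%Y-%m-%d", tz = "UTC"))
  mn <- tapply(series$temps, d, min)
  mx <- tapply(series$temps, d, max)
  data.frame(date = as.Date(names(mn)), min_C = as.numeric(mn),
             max_C = as.numeric(mx), row.names = NULL)
}
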