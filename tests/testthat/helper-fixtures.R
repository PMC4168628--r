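# Shared fixtures built in code.

make_series <- function(temps, interval_min = 30,
                        start = "2011-07-25 00:00:00", logger_id = "LT-test") {
  temperature_series(temps, start = start, interval_min = interval_min,
                     logger_id = logger_id)
}

constant_series <- function(temp_C, days, interval_min = 30, ...) {
  make_series(rep(temp_C, round(days * 1440 / interval_min)),
              interval_min = interval_min, ...)
}

make_records <- function(time_days, event = TRUE, site_id = "S01",
                         phase = 1L) {
  n <- length(time_days)
  if (n == 0L) {
    return(data.frame(device_id = character(0), site_id = character(0),
                      phase = integer(0), t0 = as.Date(character(0)),
                      time_days = numeric(0), event = logical(0)))
  }
  data.frame(device_id = sprintf("D%03d", seq_len(n)),
             site_id = rep_len(site_id, n), phase = phase,
             t0 = as.Date("2011-07-25"),
             time_days = as.numeric(time_days),
             event = rep_len(event, n), stringsAsFactors = FALSE)
}

make_calendar <- function(statuses, device_id = "D001", site_id = "S01",
                          start = "2011-07-26") {
  tti_calendar(device_id, site_id,
               dates = as.Date(start) + seq_along(statuses) - 1L,
               statuses = statuses)
}

# Draw Weibull proportional-hazards survival times:
# S(t|x) = exp(-(t/scale)^shape * exp(lp))
rweibull_ph <- function(n, shape, scale, lp = 0) {
  scale * (-log(stats::runif(n)) * exp(-lp))^(1 / shape)
}
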