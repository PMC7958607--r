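# Localized activity metrics: clock-time-bin means of log activity per day,
# and their across-day mean and standard deviation per participant. These
# complement the global cosine parameters by pinpointing when in the day
# activity level and day-to-day variability differ.

#' Per-day, per-bin mean log activity
#'
#' Splits the 24-h clock into `24/bin_hours` half-open bins (epoch membership
#' by midpoint) and averages `log_counts` over wear epochs within each
#' (day, bin) cell. Non-wear epochs are excluded, not zero-filled; a cell
#' with no wear epochs is absent from the result (missing, never zero).
#'
#' @param series an [epoch_series()] with wear mask and `log_counts`.
#' @param bin_hours positive divisor of 24 (default 4).
#' @param valid_dates optional vector of `Date`s to restrict to (valid days).
#' @return data frame `date, bin_start, bin_end, mean_activity, n_epochs`.
#' @export
bin_daily_activity <- function(series, bin_hours = 4, valid_dates = NULL) {
  stopifnot(inherits(series, "epoch_series"))
  if (bin_hours <= 0 || 24 %% bin_hours != 0)
    stop_rar("bin_hours must be a positive divisor of 24", "rar_config_error")
  if (is.null(series$log_counts))
    stop_rar("log_counts not populated; run log_transform() first",
             "rar_usage_error")
  wear <- if (is.null(series$wear)) rep(TRUE, length(series$counts))
          else series$wear
  hrs <- epoch_mid_hours(series)
  dates <- epoch_mid_date(series)
  keep <- wear
  if (!is.null(valid_dates)) keep <- keep & (dates %in% as.Date(valid_dates))
  if (!any(keep))
    return(data.frame(date = as.Date(character(0)), bin_start = numeric(0),
                      bin_end = numeric(0), mean_activity = numeric(0),
                      n_epochs = integer(0)))
  bin <- floor(hrs[keep] / bin_hours)
  key <- interaction(dates[keep], bin, drop = TRUE)
  mu <- tapply(series$log_counts[keep], key, mean)
  nn <- tapply(series$log_counts[keep], key, length)
  parts <- do.call(rbind, strsplit(names(mu), ".", fixed = TRUE))
  out <- data.frame(
    date = as.Date(parts[, 1L]),
    bin_start = as.numeric(parts[, 2L]) * bin_hours,
    mean_activity = as.numeric(mu),
    n_epochs = as.integer(nn)
  )
  out$bin_end <- out$bin_start + bin_hours
  out <- out[order(out$date, out$bin_start),
             c("date", "bin_start", "bin_end", "mean_activity", "n_epochs")]
  rownames(out) <- NULL
  attr(out, "bin_hours") <- bin_hours
  out
}

#' Across-day summary of daily bin means
#'
#' For each clock-time bin: the mean over days of the daily bin means, and
#' their sample standard deviation (n - 1 denominator) across days -- the
#' time-specific variability of daily mean-level activity. A bin observed on
#' a single day has a missing SD; a bin observed on no day has both missing.
#'
#' @param daily output of [bin_daily_activity()].
#' @param participant_id carried into the result (optional).
#' @return a `localized_metrics` data frame:
#'   `bin_start, bin_end, mean_activity, sd_activity, n_days`.
#' @export
summarize_bins <- function(daily, participant_id = NA_character_) {
  bin_hours <- attr(daily, "bin_hours")
  if (is.null(bin_hours))
    bin_hours <- if (nrow(daily)) daily$bin_end[1L] - daily$bin_start[1L] else 4
  edges <- seq(0, 24 - bin_hours, by = bin_hours)
  out <- data.frame(
    bin_start = edges,
    bin_end = edges + bin_hours,
    mean_activity = NA_real_,
    sd_activity = NA_real_,
    n_days = 0L
  )
  for (i in seq_along(edges)) {
    v <- daily$mean_activity[daily$bin_start == edges[i]]
    out$n_days[i] <- length(v)
    if (length(v) >= 1L) out$mean_activity[i] <- mean(v)
    if (length(v) >= 2L) out$sd_activity[i] <- stats::sd(v)
  }
  attr(out, "participant_id") <- participant_id
  class(out) <- c("localized_metrics", "data.frame")
  out
}

#' Localized metrics in one call
#'
#' Convenience wrapper: [bin_daily_activity()] then [summarize_bins()].
#'
#' @inheritParams bin_daily_activity
#' @return a `localized_metrics` data frame.
#' @export
localized_metrics <- function(series, bin_hours = 4, valid_dates = NULL) {
  summarize_bins(bin_daily_activity(series, bin_hours, valid_dates),
                 participant_id = series$participant_id)
}

#' Re-index a series to rise-time-aligned "person time"
#'
#' Shifts the clock so hour 0 is the participant's estimated rise time
#' (`t' = (t - up_mesor) mod 24`); binning on the result expresses activity
#' in hours since rising rather than clock hours, which adjusts localized
#' comparisons for between-person differences in rise time.
#'
#' @param series an [epoch_series()].
#' @param up_mesor rise time in hours, or a `cosine_fit` (refused if the fit
#'   did not converge).
#' @return an [epoch_series()] with all timestamps shifted by `-up_mesor` h.
#' @export
align_to_rise_time <- function(series, up_mesor) {
  stopifnot(inherits(series, "epoch_series"))
  if (inherits(up_mesor, "cosine_fit")) {
    if (!isTRUE(up_mesor$converged))
      stop_rar(sprintf(
        "participant '%s': fit did not converge; rise-time alignment refused",
        series$participant_id), "rar_usage_error")
    up_mesor <- up_mesor$up_mesor
  }
  stopifnot(is.numeric(up_mesor), length(up_mesor) == 1L)
  series$start_time <- series$start_time - up_mesor * 3600
  series
}
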