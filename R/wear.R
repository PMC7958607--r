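# Non-wear detection (Choi-style zero-run rule) and valid-day / eligible
# participant filters.

#' Flag non-wear epochs (Choi-style rule)
#'
#' An epoch is non-wear when it lies inside some qualifying interval: a run of
#' at least `window_min` minutes consisting of zero counts except for nonzero
#' interruptions totalling at most `allowance_min` minutes over the interval,
#' where every interruption burst is flanked on both sides by at least
#' `stream_min` minutes of consecutive zeros. Zero runs touching a series
#' boundary satisfy the flanking requirement (device start/stop commonly cuts
#' through sleep-time zeros). Non-wear is the union of all qualifying
#' intervals, so overlapping candidates are all honoured.
#'
#' Parameters are in minutes and converted to epochs through `epoch_seconds`;
#' for coarse epochs the window/stream lengths round up and the allowance
#' rounds down (conservative in both directions).
#'
#' @param series an [epoch_series()] with counts populated.
#' @param window_min minimum qualifying interval length, minutes (default 90).
#' @param allowance_min maximum nonzero minutes per interval (default 2).
#' @param stream_min zero-run length required either side of an interruption,
#'   minutes (default 30).
#' @return the series with its `wear` mask populated (`FALSE` = non-wear).
#' @export
detect_nonwear_choi <- function(series, window_min = 90L, allowance_min = 2L,
                                stream_min = 30L) {
  stopifnot(inherits(series, "epoch_series"))
  if (window_min <= 0 || allowance_min < 0 || stream_min <= 0)
    stop_rar("Choi parameters must be positive (allowance may be zero)",
             "rar_config_error")
  per_min <- 60 / series$epoch_seconds
  w <- as.integer(ceiling(window_min * per_min))
  a <- as.integer(floor(allowance_min * per_min))
  s <- as.integer(ceiling(stream_min * per_min))
  x <- series$counts
  n <- length(x)
  series$wear <- !choi_nonwear_mask(x, w, a, s)
  series
}

# Core mask computation on a count vector; returns TRUE where non-wear.
# Qualifying intervals start and end on zero epochs, so interruptions are
# whole bursts strictly interior to the interval. Route: run-length encode,
# mark each burst valid when its adjacent zero runs are >= s epochs (or
# touch a series edge), then extend from each zero run through consecutive
# valid bursts while the burst total stays within the allowance; mark the
# extension when it reaches the window length. The union of such maximal
# extensions equals the union of all qualifying intervals, because widening
# a qualifying interval to run boundaries only adds zeros.
choi_nonwear_mask <- function(x, w, a, s) {
  n <- length(x)
  if (n == 0L) return(logical(0))
  nz <- x != 0L
  if (!any(nz)) return(rep(n >= w, n))
  r <- rle(nz)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  burst <- r$values
  # validity of each run viewed as an interruption (only meaningful for
  # interior bursts, which always have zero runs on both sides)
  left_ok <- c(FALSE, r$lengths[-k] >= s | starts[-k] == 1L)
  right_ok <- c(r$lengths[-1L] >= s | ends[-1L] == n, FALSE)
  ok_burst <- burst & left_ok & right_ok
  out <- logical(n)
  for (u in which(!burst)) {
    total <- 0L
    v <- u
    j <- u + 1L
    while (j + 1L <= k && ok_burst[j] &&
           total + r$lengths[j] <= a && !burst[j + 1L]) {
      total <- total + r$lengths[j]
      v <- j + 1L
      j <- j + 2L
    }
    if (ends[v] - starts[u] + 1L >= w) out[starts[u]:ends[v]] <- TRUE
  }
  out
}

#' Per-day wear summary and valid-day flags
#'
#' A valid wear day has at least `min_wear_minutes` of wear (default 600,
#' i.e. 10 h, boundary inclusive). Days are calendar dates of epoch
#' midpoints.
#'
#' @param series an [epoch_series()] with the wear mask populated.
#' @param min_wear_minutes valid-day threshold in minutes (default 600).
#' @param min_valid_days eligibility threshold in days (default 3).
#' @return a `wear_summary`: list with `participant_id`, a per-day data frame
#'   (`date`, `wear_minutes`, `valid_day`), `n_valid_days` and `eligible`.
#' @export
daily_wear_summary <- function(series, min_wear_minutes = 600L,
                               min_valid_days = 3L) {
  stopifnot(inherits(series, "epoch_series"))
  if (is.null(series$wear))
    stop_rar("wear mask not populated; run detect_nonwear_choi() first",
             "rar_usage_error")
  dates <- epoch_mid_date(series)
  mins_per_epoch <- series$epoch_seconds / 60
  wear_by_day <- tapply(series$wear, dates, sum) * mins_per_epoch
  days <- data.frame(
    date = as.Date(names(wear_by_day)),
    wear_minutes = as.numeric(wear_by_day),
    row.names = NULL
  )
  days$valid_day <- days$wear_minutes >= min_wear_minutes
  structure(
    list(participant_id = series$participant_id,
         days = days,
         n_valid_days = sum(days$valid_day),
         eligible = sum(days$valid_day) >= min_valid_days),
    class = "wear_summary"
  )
}

#' @export
print.wear_summary <- function(x, ...) {
  cat(sprintf("<wear_summary> %s: %d/%d valid days, %s\n",
              x$participant_id, x$n_valid_days, nrow(x$days),
              if (x$eligible) "eligible" else "excluded"))
  invisible(x)
}

#' Eligible participants under the valid-day rule
#'
#' @param summaries list of `wear_summary` objects.
#' @param min_valid_days minimum number of valid days (default 3).
#' @return sorted character vector of eligible participant ids.
#' @export
filter_valid_participants <- function(summaries, min_valid_days = 3L) {
  if (!length(summaries)) return(character(0))
  ids <- vapply(summaries, function(s) s$participant_id, character(1))
  nv <- vapply(summaries, function(s) sum(s$days$valid_day), integer(1))
  sort(ids[nv >= min_valid_days])
}
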