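# Minute-epoch activity count series: construction, I/O, midnight truncation,
# log transform. Timestamps are naive local clock time (stored as POSIXct in
# UTC so no daylight-saving arithmetic is ever applied); series with repeated
# timestamps are refused.

#' Construct an epoch series
#'
#' An `epoch_series` holds one participant's contiguous, fixed-width epoch
#' activity counts, plus optional wear mask and cached log-transformed counts.
#' Epoch `i` covers `[start_time + (i-1)*epoch_seconds,
#' start_time + i*epoch_seconds)`.
#'
#' @param participant_id character scalar.
#' @param start_time `POSIXct` (UTC, interpreted as local clock time) or an
#'   ISO-8601 string `"YYYY-MM-DDTHH:MM:SS"`.
#' @param counts integer vector of non-negative activity counts, one per epoch.
#' @param epoch_seconds positive integer epoch width in seconds (default 60).
#' @param wear optional logical vector parallel to `counts`.
#' @param log_counts optional numeric vector parallel to `counts`; when
#'   present must equal `log(counts + 1)`.
#' @return an object of class `epoch_series`.
#' @export
epoch_series <- function(participant_id, start_time, counts,
                         epoch_seconds = 60L, wear = NULL, log_counts = NULL) {
  stopifnot(length(participant_id) == 1L, length(epoch_seconds) == 1L)
  if (is.character(start_time)) start_time <- parse_epoch_time(start_time)
  stopifnot(inherits(start_time, "POSIXct"), length(start_time) == 1L)
  attr(start_time, "tzone") <- "UTC"
  epoch_seconds <- as.integer(epoch_seconds)
  if (is.na(epoch_seconds) || epoch_seconds <= 0L)
    stop_rar("epoch_seconds must be a positive integer", "rar_config_error")
  counts <- as.integer(round(counts))
  if (any(is.na(counts)))
    stop_rar("counts contain missing values", "rar_data_error")
  if (any(counts < 0L))
    stop_rar(sprintf("negative count for participant '%s'", participant_id),
             "rar_data_error")
  n <- length(counts)
  if (!is.null(wear)) {
    wear <- as.logical(wear)
    if (length(wear) != n)
      stop_rar("wear mask length differs from counts", "rar_data_error")
  }
  if (!is.null(log_counts)) {
    if (length(log_counts) != n)
      stop_rar("log_counts length differs from counts", "rar_data_error")
    if (max(abs(log_counts - log(counts + 1))) > 1e-8)
      stop_rar("log_counts do not equal log(counts + 1)", "rar_data_error")
  }
  structure(
    list(participant_id = as.character(participant_id),
         start_time = start_time,
         epoch_seconds = epoch_seconds,
         counts = counts,
         wear = wear,
         log_counts = log_counts),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> participant %s: %d epochs of %ds from %s%s%s\n",
    x$participant_id, length(x$counts), x$epoch_seconds,
    format(x$start_time, "%Y-%m-%dT%H:%M:%S"),
    if (!is.null(x$wear)) sprintf(", %.0f%% wear", 100 * mean(x$wear)) else "",
    if (!is.null(x$log_counts)) ", log-transformed" else ""))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

parse_epoch_time <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  if (any(is.na(out) & !is.na(x)))
    stop_rar(sprintf("unparseable ISO-8601 timestamp: '%s'",
                     x[which(is.na(out))[1L]]), "rar_format_error")
  out
}

# Contiguous positional subset; start_time advances accordingly.
es_window <- function(x, from, to) {
  idx <- seq.int(from, to)
  epoch_series(
    x$participant_id,
    x$start_time + (from - 1) * x$epoch_seconds,
    x$counts[idx],
    x$epoch_seconds,
    wear = if (!is.null(x$wear)) x$wear[idx],
    log_counts = if (!is.null(x$log_counts)) x$log_counts[idx]
  )
}

# Hour-of-day of each epoch midpoint, in [0, 24).
epoch_mid_hours <- function(x) {
  sec0 <- as.numeric(x$start_time) %% 86400
  n <- length(x$counts)
  ((sec0 + (seq_len(n) - 0.5) * x$epoch_seconds) %% 86400) / 3600
}

# Calendar date of each epoch midpoint.
epoch_mid_date <- function(x) {
  n <- length(x$counts)
  as.Date(x$start_time + (seq_len(n) - 0.5) * x$epoch_seconds, tz = "UTC")
}

#' Read minute-epoch activity counts from CSV
#'
#' Expects columns `participant_id,timestamp,count` (header required,
#' ISO-8601 timestamps). An optional `axis` column is ignored with a warning.
#' Rows are sorted by timestamp within participant; duplicated timestamps and
#' gaps are errors -- no silent resampling is ever performed.
#'
#' @param path CSV file path.
#' @param epoch_seconds expected epoch spacing in seconds (default 60).
#' @return named list of [epoch_series()], one per participant, sorted by id.
#' @export
read_epoch_csv <- function(path, epoch_seconds = 60L) {
  if (!file.exists(path))
    stop_rar(sprintf("file not found: %s", path), "rar_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  required <- c("participant_id", "timestamp", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_rar(sprintf("missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "rar_format_error")
  if ("axis" %in% names(df)) {
    warning("column 'axis' present and ignored")
    df$axis <- NULL
  }
  if (any(is.na(df$count) | df$count < 0))
    stop_rar("negative or missing count value", "rar_data_error")
  ts <- parse_epoch_time(df$timestamp)
  out <- lapply(split(seq_len(nrow(df)), df$participant_id), function(idx) {
    pid <- df$participant_id[idx[1L]]
    o <- order(ts[idx])
    tt <- ts[idx][o]
    if (anyDuplicated(as.numeric(tt)))
      stop_rar(sprintf("duplicated timestamp for participant '%s'", pid),
               "rar_data_error")
    d <- diff(as.numeric(tt))
    if (length(d) && any(d != epoch_seconds)) {
      at <- which(d != epoch_seconds)[1L]
      stop_rar(sprintf(
        "gap in epochs for participant '%s' after %s (%.0f s, expected %d s)",
        pid, format(tt[at], "%Y-%m-%dT%H:%M:%S"), d[at], epoch_seconds),
        "rar_data_error")
    }
    epoch_series(pid, tt[1L], df$count[idx][o], epoch_seconds)
  })
  out[order(names(out))]
}

#' Write an epoch series to CSV
#'
#' Inverse of [read_epoch_csv()]: emits `participant_id,timestamp,count` with
#' ISO-8601 timestamps and integer counts. A zero-length series yields a
#' header-only file.
#'
#' @param series an [epoch_series()].
#' @param path output file path.
#' @param append append without header (used to combine participants).
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path, append = FALSE) {
  stopifnot(inherits(series, "epoch_series"))
  n <- length(series$counts)
  df <- data.frame(
    participant_id = rep(series$participant_id, n),
    timestamp = format(series$start_time +
                         (seq_len(n) - 1) * series$epoch_seconds,
                       "%Y-%m-%dT%H:%M:%S"),
    count = series$counts
  )
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = !append, append = append, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_rar(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
             "rar_io_error")
  invisible(path)
}

#' Truncate a series to whole midnight-to-midnight days
#'
#' Keeps the half-open window from the first local midnight at or after
#' `start_time` to the midnight `n_days` later (the epoch beginning at the
#' ending midnight is excluded). The default window, first to sixth midnight,
#' yields five complete days. If the series ends early the result is
#' truncated to what is available with a warning, never an error.
#'
#' @param series an [epoch_series()].
#' @param n_days number of whole days to keep (default 5).
#' @return truncated [epoch_series()].
#' @export
truncate_to_midnights <- function(series, n_days = 5L) {
  stopifnot(inherits(series, "epoch_series"), n_days >= 1)
  es <- series$epoch_seconds
  sec0 <- as.numeric(series$start_time) %% 86400
  off <- (86400 - sec0) %% 86400          # seconds until first midnight
  i0 <- ceiling(off / es) + 1L            # first epoch starting at/after it
  if (off == 0) i0 <- 1L
  n <- length(series$counts)
  if (i0 > n)
    stop_rar(sprintf("series for participant '%s' contains no midnight",
                     series$participant_id), "rar_data_error")
  i1 <- i0 - 1L + as.integer(n_days * 86400 / es)
  if (i1 > n) {
    warning(sprintf(
      "participant '%s': only %.2f of %d requested days available; truncated",
      series$participant_id, (n - i0 + 1) * es / 86400, n_days))
    i1 <- n
  }
  es_window(series, i0, i1)
}

#' Cache the log scale used by all modelling stages
#'
#' Populates `log_counts = log(counts + 1)`; counts are untouched. Computed
#' once and carried so every downstream stage sees bit-identical inputs.
#'
#' @param series an [epoch_series()].
#' @return the series with `log_counts` populated.
#' @export
log_transform <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  series$log_counts <- log(series$counts + 1)
  series
}
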