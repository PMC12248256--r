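# Preprocessing chain: 1 Hz resampling of the 24-s environmental stream,
# block-averaging of the 10 Hz physiological stream to the same 1 Hz grid,
# timestamp segmentation into 7 static + 7 dynamic arrays, and length
# normalization by linear interpolation at 3 samples per minute so segments
# are comparable across participants.

#' Resample a timestamped stream to 1 Hz by linear interpolation
#'
#' Produces values on a 1-second grid starting at the stream's first
#' timestamp and ending at its last whole second, linearly interpolating
#' between bracketing records (endpoints preserved; no extrapolation).
#'
#' @param stream data.frame with a `timestamp` column (seconds) and the
#'   requested channel column.
#' @param channel channel column name.
#' @return object of class `uniform_series`: list with `start_ts`,
#'   `rate_hz = 1`, `times`, `values`, `channel`.
#' @export
resample_to_1hz <- function(stream, channel) {
  if (!channel %in% names(stream))
    abort_pape(sprintf("channel '%s' not present in stream", channel), "pape_io_error")
  t <- stream$timestamp
  v <- stream[[channel]]
  if (length(t) < 2)
    abort_pape("cannot resample a stream with fewer than 2 records", "pape_preprocess_error")
  if (any(diff(t) <= 0))
    abort_pape("stream timestamps must be strictly increasing", "pape_preprocess_error")
  grid <- seq(t[1], t[length(t)], by = 1)
  vals <- stats::approx(t, v, xout = grid, method = "linear")$y
  uniform_series(start_ts = grid[1], rate_hz = 1, times = grid,
                 values = vals, channel = channel)
}

#' Block-average a high-rate stream to 1 Hz
#'
#' Averages all samples falling in each whole second; used to bring the
#' 10 Hz physiological channels onto the same 1 Hz representation as the
#' environmental channels before segmentation.
#'
#' @inheritParams resample_to_1hz
#' @return a `uniform_series` at 1 Hz.
#' @export
block_average_1hz <- function(stream, channel) {
  if (!channel %in% names(stream))
    abort_pape(sprintf("channel '%s' not present in stream", channel), "pape_io_error")
  t <- stream$timestamp
  if (length(t) < 2)
    abort_pape("cannot average a stream with fewer than 2 records", "pape_preprocess_error")
  if (any(diff(t) <= 0))
    abort_pape("stream timestamps must be strictly increasing", "pape_preprocess_error")
  sec <- floor(t)
  m <- tapply(stream[[channel]], sec, mean)
  times <- as.numeric(names(m))
  if (any(diff(times) != 1)) {
    # gaps: interpolate the per-second means onto a full 1 Hz grid
    grid <- seq(times[1], times[length(times)], by = 1)
    vals <- stats::approx(times, as.numeric(m), xout = grid)$y
    times <- grid
    m <- vals
  }
  uniform_series(start_ts = times[1], rate_hz = 1, times = times,
                 values = as.numeric(m), channel = channel)
}

uniform_series <- function(start_ts, rate_hz, times, values, channel) {
  if (rate_hz <= 0) abort_pape("rate_hz must be > 0", "pape_preprocess_error")
  if (any(!is.finite(values)))
    abort_pape(sprintf("non-finite values in channel '%s'", channel),
               "pape_preprocess_error")
  structure(list(start_ts = start_ts, rate_hz = rate_hz, times = times,
                 values = values, channel = channel),
            class = "uniform_series")
}

#' Cut a uniform series into static and dynamic segments
#'
#' Static segments take samples with `arrive_ts <= t < leave_ts` (half-open,
#' so adjacent segments never share a sample); dynamic segments are the gaps
#' between consecutive static points, including the final transit after the
#' last point up to the end of the series.
#'
#' @param series a `uniform_series`.
#' @param plan segment plan data.frame with `label`, `arrive_ts`, `leave_ts`.
#' @return list with named lists `static` (label -> numeric vector) and
#'   `dynamic` (`"A>B"` style keys -> numeric vector).
#' @export
segment_series <- function(series, plan) {
  stopifnot(inherits(series, "uniform_series"))
  t <- series$times
  span <- range(t)
  static <- list()
  dynamic <- list()
  n <- nrow(plan)
  for (i in seq_len(n)) {
    if (plan$arrive_ts[i] < span[1] || plan$leave_ts[i] > span[2] + 1)
      abort_pape(sprintf("segment '%s' [%g, %g) lies outside the series span [%g, %g]",
                         plan$label[i], plan$arrive_ts[i], plan$leave_ts[i],
                         span[1], span[2]),
                 "pape_preprocess_error")
    sel <- t >= plan$arrive_ts[i] & t < plan$leave_ts[i]
    static[[plan$label[i]]] <- series$values[sel]
    to <- if (i < n) plan$label[i + 1] else "end"
    t1 <- if (i < n) plan$arrive_ts[i + 1] else span[2] + 1
    sel_d <- t >= plan$leave_ts[i] & t < t1
    if (any(sel_d))
      dynamic[[paste0(plan$label[i], ">", to)]] <- series$values[sel_d]
  }
  list(static = static, dynamic = dynamic)
}

#' Normalize a segment to a fixed number of samples per minute
#'
#' Linearly interpolates a 1 Hz segment onto `round(duration_min *
#' samples_per_minute)` evenly spaced nodes spanning the segment including
#' both endpoints, so every participant contributes the same number of
#' samples per segment (15 for a 5-minute dwell at the default 3 per
#' minute).
#'
#' @param values numeric segment sampled at `rate_hz`.
#' @param samples_per_minute target density (default 3).
#' @param rate_hz input sampling rate (default 1).
#' @return numeric vector of the normalized nodes.
#' @export
normalize_length <- function(values, samples_per_minute = 3, rate_hz = 1) {
  n <- length(values)
  if (n < 2)
    abort_pape("cannot normalize a segment with fewer than 2 samples",
               "pape_preprocess_error")
  duration_min <- n / (60 * rate_hz)
  m <- round(duration_min * samples_per_minute)
  if (m < 2) m <- 2
  idx <- seq(0, n - 1, length.out = m)
  stats::approx(seq(0, n - 1), values, xout = idx)$y
}

#' Preprocess one channel of a session into a segmented channel
#'
#' Full chain: resample to 1 Hz (environmental channels) or block-average to
#' 1 Hz (the 10 Hz physiological channels `pr` and `rr`), segment by the
#' session's plan, and length-normalize every segment.
#'
#' @param session a `sensor_session`.
#' @param channel channel name (environmental column or `"pr"`/`"rr"`).
#' @param samples_per_minute node density after normalization (default 3).
#' @return object of class `segmented_channel`: list with `channel`,
#'   `samples_per_minute`, `static` and `dynamic` named lists of
#'   normalized arrays, and `dwell_min` per static segment.
#' @export
preprocess_channel <- function(session, channel, samples_per_minute = 3) {
  stopifnot(inherits(session, "sensor_session"))
  physio <- channel %in% c("pr", "rr")
  series <- if (physio) {
    block_average_1hz(session$physio_stream, channel)
  } else {
    resample_to_1hz(session$env_stream, channel)
  }
  segs <- segment_series(series, session$segment_plan)
  norm <- function(x) normalize_length(x, samples_per_minute, rate_hz = 1)
  structure(list(
    channel = channel,
    samples_per_minute = samples_per_minute,
    static = lapply(segs$static, norm),
    dynamic = lapply(segs$dynamic, norm),
    dwell_min = (session$segment_plan$leave_ts - session$segment_plan$arrive_ts) / 60
  ), class = "segmented_channel")
}

#' Preprocess all analysis channels of a session
#'
#' @param session a `sensor_session`.
#' @param channels channels to process; defaults to the dose-relevant
#'   pollutants plus the physiological channels (CO and NO2 are excluded:
#'   they are censored at the detection limit throughout).
#' @param samples_per_minute node density after normalization.
#' @return named list of `segmented_channel` objects.
#' @export
preprocess_session <- function(session,
                               channels = c("pm1", "pm2_5", "pm10", "co2",
                                            "tvoc", "pr", "rr"),
                               samples_per_minute = 3) {
  out <- lapply(channels, function(ch)
    preprocess_channel(session, ch, samples_per_minute))
  names(out) <- channels
  out
}

#' Tidy long-format export of segmented channels
#'
#' @param segmented named list of `segmented_channel` objects (one session).
#' @param participant_id identifier stamped on every row.
#' @return data.frame with columns participant, channel, segment,
#'   segment_type, node_index, value.
#' @export
segments_to_df <- function(segmented, participant_id) {
  rows <- list()
  for (ch in names(segmented)) {
    sc <- segmented[[ch]]
    for (type in c("static", "dynamic")) {
      for (key in names(sc[[type]])) {
        v <- sc[[type]][[key]]
        rows[[length(rows) + 1L]] <- data.frame(
          participant = participant_id, channel = ch, segment = key,
          segment_type = type, node_index = seq_along(v), value = v,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
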