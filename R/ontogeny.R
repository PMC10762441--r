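#' Daily ontogeny summaries
#'
#' Aggregates a typed-dive table into one row per day since departure:
#' the daily median drift rate (over that day's drift dives only — a day with
#' no drift dive has a missing median, never 0), the 95th daily percentiles
#' of maximum dive depth and dive duration (linear interpolation between
#' order statistics, `quantile` type 7), the dive count, per-type counts, and
#' day/night counts when a `day_night` column is present.
#'
#' Days are binned from the trip start (UTC), not local midnight:
#' `day = floor((dive_start - trip_start) / 86400)`.
#'
#' @param typed a [classify_dives()] table (optionally with `day_night`).
#' @param trip_start POSIXct departure time; defaults to the first dive start.
#' @return data frame with one row per day that has at least one dive:
#'   `individual_id`, `day`, `n_dives`, `median_drift_rate`, `p95_depth`,
#'   `p95_duration`, `n_active_bottom`, `n_drift`, `n_benthic`, `n_transit`,
#'   `n_day`, `n_night`.
#' @export
daily_summaries <- function(typed, trip_start = NULL) {
  if (!nrow(typed)) stop("no dives to summarize")
  trip_start <- trip_start %||% min(typed$start_time)
  day <- floor((as.numeric(typed$start_time) - as.numeric(trip_start)) / 86400)
  has_dn <- "day_night" %in% names(typed)
  id <- if ("individual_id" %in% names(typed)) typed$individual_id[1] else NA_character_
  rows <- lapply(sort(unique(day)), function(d) {
    g <- typed[day == d, ]
    dr <- g$drift_rate_ms[g$dive_type == "drift"]
    dr <- dr[is.finite(dr)]
    data.frame(
      individual_id = id, day = d, n_dives = nrow(g),
      median_drift_rate = if (length(dr)) stats::median(dr) else NA_real_,
      p95_depth = stats::quantile(g$max_depth, 0.95, names = FALSE, type = 7),
      p95_duration = stats::quantile(g$duration, 0.95, names = FALSE, type = 7),
      n_active_bottom = sum(g$dive_type == "active_bottom"),
      n_drift = sum(g$dive_type == "drift"),
      n_benthic = sum(g$dive_type == "benthic"),
      n_transit = sum(g$dive_type == "transit"),
      n_day = if (has_dn) sum(g$day_night == "day", na.rm = TRUE) else NA_integer_,
      n_night = if (has_dn) sum(g$day_night == "night", na.rm = TRUE) else NA_integer_)
  })
  do.call(rbind, rows)
}

#' Neutral-buoyancy crossing days
#'
#' Smooths the daily median drift-rate series with a running median (default
#' 7-day window) and returns the fractional days at which the smoothed series
#' changes sign — the days the animal crosses neutral buoyancy. Days without
#' a drift-rate value are skipped; crossings are linearly interpolated
#' between the bracketing valued days. A series that never changes sign
#' yields an empty result.
#'
#' @param daily a [daily_summaries()] data frame.
#' @param smoothing_window running-median window in days (forced odd).
#' @return numeric vector of fractional crossing days, ordered.
#' @export
buoyancy_crossings <- function(daily, smoothing_window = 7) {
  ok <- is.finite(daily$median_drift_rate)
  d <- daily$day[ok]
  v <- daily$median_drift_rate[ok]
  if (length(v) < 2) stop("need at least 2 days with drift-rate values")
  k <- max(1L, min(as.integer(smoothing_window), length(v)))
  if (k %% 2L == 0L) k <- k - 1L
  s <- if (k >= 3L) stats::runmed(v, k, endrule = "median") else v
  sgn <- sign(s)
  # sign() can be 0; propagate the previous sign through exact zeros
  for (i in seq_along(sgn)[-1]) if (sgn[i] == 0) sgn[i] <- sgn[i - 1]
  ch <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(ch)) return(numeric(0))
  vapply(ch, function(i) {
    d[i] + (0 - s[i]) * (d[i + 1] - d[i]) / (s[i + 1] - s[i])
  }, numeric(1))
}

#' Plot daily ontogeny curves
#'
#' Three stacked panels against day since departure: 95th-percentile maximum
#' depth (axis inverted, deeper downward), 95th-percentile dive duration, and
#' daily median drift rate with the neutral-buoyancy line and any detected
#' crossings marked.
#'
#' @param daily a [daily_summaries()] data frame.
#' @param smoothing_window passed to [buoyancy_crossings()].
#' @return invisibly, the crossing days.
#' @export
plot_daily_summaries <- function(daily, smoothing_window = 7) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1), mgp = c(2, 0.6, 0))
  on.exit(graphics::par(op))
  graphics::plot(daily$day, daily$p95_depth, type = "l", ylim = rev(range(daily$p95_depth)),
                 xlab = "", ylab = "p95 depth (m)")
  graphics::plot(daily$day, daily$p95_duration / 60, type = "l",
                 xlab = "", ylab = "p95 duration (min)")
  graphics::plot(daily$day, daily$median_drift_rate, type = "p", pch = 16, cex = 0.5,
                 xlab = "day since departure", ylab = "drift rate (m/s)")
  graphics::abline(h = 0, lty = 2)
  cr <- tryCatch(buoyancy_crossings(daily, smoothing_window),
                 error = function(e) numeric(0))
  if (length(cr)) graphics::abline(v = cr, col = "grey50", lty = 3)
  invisible(cr)
}

#' Write daily summaries to CSV
#' @param daily a [daily_summaries()] data frame.
#' @param path output path.
#' @param params optional [dive_params()] header.
#' @return `path`, invisibly.
#' @export
write_daily_summaries <- function(daily, path, params = NULL) {
  write_csv_with_header(daily, path, params)
}
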