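#' Time-depth series
#'
#' Container for one individual's regularly sampled depth record. Depth is in
#' metres, positive downward, with the sea surface at 0. Times are UTC.
#'
#' @param individual_id character scalar identifying the animal/tag.
#' @param times `POSIXct` (UTC) or numeric seconds; must be strictly
#'   increasing.
#' @param depths numeric depths in metres, positive downward; must be finite.
#' @param dt nominal sampling interval in seconds; inferred from the median
#'   time step when `NULL`.
#'
#' @return An object of class `"tdr_series"`: a list with elements
#'   `individual_id`, `time` (POSIXct, UTC), `depth`, `dt`.
#' @seealso [read_tdr()], [downsample_tdr()], [tdr_gaps()]
#' @export
tdr_series <- function(individual_id, times, depths, dt = NULL) {
  if (length(times) != length(depths)) {
    stop("times and depths must have equal length")
  }
  if (length(times) < 2) stop("a tdr_series needs at least 2 samples")
  if (is.numeric(times)) {
    times <- as.POSIXct(times, origin = "1970-01-01", tz = "UTC")
  }
  if (!inherits(times, "POSIXct")) stop("times must be POSIXct or numeric seconds")
  attr(times, "tzone") <- "UTC"
  steps <- diff(as.numeric(times))
  if (any(steps <= 0)) {
    i <- which(steps <= 0)[1]
    stop(sprintf("times not strictly increasing at row %d", i + 1L))
  }
  if (any(!is.finite(depths))) {
    i <- which(!is.finite(depths))[1]
    stop(sprintf("non-finite depth at row %d", i))
  }
  if (is.null(dt)) dt <- stats::median(steps)
  structure(
    list(individual_id = as.character(individual_id)[1],
         time = times, depth = as.numeric(depths), dt = dt),
    class = "tdr_series")
}

#' @export
print.tdr_series <- function(x, ...) {
  cat(sprintf("<tdr_series> id=%s  n=%d  dt=%gs  %s .. %s  depth 0..%.1f m\n",
              x$individual_id, length(x$depth), x$dt,
              format(x$time[1], "%Y-%m-%d %H:%M:%S"),
              format(x$time[length(x$time)], "%Y-%m-%d %H:%M:%S"),
              max(x$depth)))
  invisible(x)
}

#' @export
as.data.frame.tdr_series <- function(x, ...) {
  data.frame(individual_id = x$individual_id,
             timestamp_utc = x$time, depth_m = x$depth)
}

#' Sampling gaps in a series
#'
#' A gap is any step between consecutive samples that deviates from the
#' nominal interval by more than `dt/2`.
#'
#' @param series a [tdr_series()].
#' @return data frame with columns `after_row`, `start`, `end`, `gap_s`;
#'   zero rows when the record is regular.
#' @export
tdr_gaps <- function(series) {
  steps <- diff(as.numeric(series$time))
  i <- which(abs(steps - series$dt) > series$dt / 2)
  data.frame(after_row = i,
             start = series$time[i],
             end = series$time[i + 1L],
             gap_s = steps[i])
}

#' Split a series at long gaps
#'
#' Gaps longer than `max_gap` (default 10 sampling intervals) split the record
#' into segments that are processed independently downstream.
#'
#' @param series a [tdr_series()].
#' @param max_gap seconds; default `10 * series$dt`.
#' @return list of `tdr_series` segments (length 1 when there is no long gap).
#' @export
split_on_gaps <- function(series, max_gap = 10 * series$dt) {
  steps <- diff(as.numeric(series$time))
  cut <- which(steps > max_gap)
  if (!length(cut)) return(list(series))
  bounds <- c(0L, cut, length(series$depth))
  lapply(seq_len(length(bounds) - 1L), function(k) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    tdr_series(series$individual_id, series$time[idx], series$depth[idx],
               dt = series$dt)
  })
}

#' Read a time-depth CSV
#'
#' The `simple` dialect expects columns `timestamp_utc` (ISO-8601, UTC) and
#' `depth_m`, plus optionally `individual_id`. The `wide` dialect accepts any
#' file containing the declared time/depth columns and ignores the rest.
#' Leading `#` comment lines (parameter headers written by this package) are
#' skipped.
#'
#' @param path CSV file path.
#' @param dialect `"simple"` or `"wide"`.
#' @param time_col,depth_col,id_col column names (used by the `wide` dialect;
#'   the defaults match `simple`).
#' @param individual_id overrides/supplies the id when the file has no id
#'   column.
#' @param dt nominal sampling interval; inferred when `NULL`.
#' @return a [tdr_series()].
#' @export
read_tdr <- function(path, dialect = c("simple", "wide"),
                     time_col = "timestamp_utc", depth_col = "depth_m",
                     id_col = "individual_id", individual_id = NULL,
                     dt = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c(time_col, depth_col)) {
    if (!col %in% names(df)) stop(sprintf("column '%s' not found in %s", col, path))
  }
  tm <- parse_utc(df[[time_col]])
  if (anyNA(tm)) {
    stop(sprintf("unparseable timestamp at row %d: '%s'",
                 which(is.na(tm))[1], df[[time_col]][which(is.na(tm))[1]]))
  }
  id <- individual_id %||%
    (if (id_col %in% names(df)) df[[id_col]][1] else basename(path))
  dep <- suppressWarnings(as.numeric(df[[depth_col]]))
  if (any(!is.finite(dep))) {
    stop(sprintf("non-finite depth at row %d", which(!is.finite(dep))[1]))
  }
  tdr_series(id, tm, dep, dt = dt)
}

#' Write a time-depth CSV (simple dialect)
#'
#' @param series a [tdr_series()].
#' @param path output path.
#' @param params optional [dive_params()] serialized as `#` comment header.
#' @return `path`, invisibly.
#' @export
write_tdr <- function(series, path, params = NULL) {
  write_csv_with_header(as.data.frame(series), path, params)
}

#' Read / write a sparse location track
#'
#' Track CSVs have columns `timestamp_utc`, `lon`, `lat`. Longitudes are
#' degrees east in (-180, 180], latitudes degrees north.
#'
#' @param path CSV path.
#' @param speed_cap maximum plausible speed (m/s) used for validation; implied
#'   speeds above it raise a warning (fixes are retained).
#' @return data frame of class `"dive_track"` with `time`, `lon`, `lat`.
#' @export
read_track <- function(path, speed_cap = 3) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tm <- parse_utc(df$timestamp_utc)
  if (anyNA(tm)) stop(sprintf("unparseable track timestamp at row %d", which(is.na(tm))[1]))
  make_track(tm, df$lon, df$lat, speed_cap = speed_cap)
}

#' @rdname read_track
#' @param track a track data frame.
#' @param params optional [dive_params()] serialized as comment header.
#' @export
write_track <- function(track, path, params = NULL) {
  df <- data.frame(timestamp_utc = track$time, lon = track$lon, lat = track$lat)
  write_csv_with_header(df, path, params)
}

#' Construct a validated track
#'
#' @param times POSIXct (UTC) or numeric seconds, strictly increasing.
#' @param lons,lats coordinates in degrees.
#' @param speed_cap m/s; implied speeds above this raise a warning.
#' @return data frame of class `"dive_track"`.
#' @export
make_track <- function(times, lons, lats, speed_cap = 3) {
  if (is.numeric(times)) times <- as.POSIXct(times, origin = "1970-01-01", tz = "UTC")
  attr(times, "tzone") <- "UTC"
  stopifnot(length(times) == length(lons), length(lons) == length(lats))
  if (is.unsorted(times, strictly = TRUE)) stop("track times must be strictly increasing")
  if (any(lats < -90 | lats > 90)) stop("latitude out of [-90, 90]")
  lons <- wrap_lon(lons)
  tr <- data.frame(time = times, lon = lons, lat = lats)
  class(tr) <- c("dive_track", "data.frame")
  if (nrow(tr) > 1) {
    d <- geosphere::distCosine(cbind(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)]),
                               cbind(tr$lon[-1], tr$lat[-1]))
    sp <- d / diff(as.numeric(tr$time))
    if (any(sp > speed_cap)) {
      warning(sprintf("track implies speeds above %g m/s (max %.2f); fixes retained",
                      speed_cap, max(sp)))
    }
  }
  tr
}

#' Decimate a series to a coarser sampling interval
#'
#' Samples at times congruent to the first timestamp modulo `target_dt` are
#' retained; no interpolation or averaging is performed, so instantaneous
#' depths are preserved. `target_dt` must be an integer multiple of the
#' series' interval. Decimation at the series' own interval is the identity
#' and the operation is idempotent.
#'
#' @param series a [tdr_series()].
#' @param target_dt target interval in seconds.
#' @return a [tdr_series()] at `target_dt`.
#' @export
downsample_tdr <- function(series, target_dt) {
  r <- target_dt / series$dt
  if (abs(r - round(r)) > 1e-9 || r < 1) {
    stop("target_dt must be an integer multiple of the series interval")
  }
  if (round(r) == 1L) return(series)
  off <- as.numeric(series$time) - as.numeric(series$time[1])
  keep <- abs(off %% target_dt) < 1e-6 | abs(off %% target_dt - target_dt) < 1e-6
  tdr_series(series$individual_id, series$time[keep], series$depth[keep],
             dt = target_dt)
}

parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d")) {
    idx <- is.na(out)
    if (!any(idx)) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
  }
  out
}

write_csv_with_header <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) writeLines(params_header(params), con)
  tc <- vapply(df, function(v) inherits(v, "POSIXct"), logical(1))
  df[tc] <- lapply(df[tc], format, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

wrap_lon <- function(lon) {
  w <- ((lon + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
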