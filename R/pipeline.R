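#' Run the full processing chain on one record
#'
#' Orchestrates the whole analysis for one individual: optional decimation to
#' the analysis resolution, zero-offset correction, dive detection, phase
#' segmentation and classification, day/night assignment from the track, and
#' daily ontogeny summaries. Deterministic given inputs and parameters.
#'
#' @param series a raw [tdr_series()].
#' @param track optional track data frame; without it the pipeline completes
#'   in a degraded mode with day/night labels absent (warning).
#' @param params a [dive_params()].
#' @param trip_start POSIXct departure; defaults to the first sample time.
#' @param out_dir optional directory; when given, writes `dives.csv`,
#'   `daily.csv` and `manifest.json` (parameters, stage counts, package
#'   version) there.
#' @return list of class `"dive_pipeline"` with `series` (corrected),
#'   `dives` (typed dive table), `daily`, `manifest`.
#' @export
run_pipeline <- function(series, track = NULL, params = dive_params(),
                         trip_start = NULL, out_dir = NULL) {
  stopifnot(inherits(series, "tdr_series"))
  n_raw <- length(series$depth)
  if (series$dt < params$target_dt) {
    r <- params$target_dt / series$dt
    if (abs(r - round(r)) < 1e-9) {
      series <- downsample_tdr(series, params$target_dt)
    } else {
      warning("series interval does not divide target_dt; left at native resolution")
    }
  }
  corrected <- zero_offset_correct(series, window = params$zoc_window,
                                   guard_depth = params$zoc_guard_depth,
                                   probs = params$zoc_quantile)
  dives <- detect_dives(corrected, params = params)
  typed <- classify_dives(corrected, dives, params)
  typed$individual_id <- series$individual_id
  typed <- if (!is.null(track)) {
    assign_day_night(typed, track, zenith = params$solar_zenith,
                     speed_cap = params$speed_cap)
  } else {
    typed$lon <- NA_real_; typed$lat <- NA_real_
    typed$day_night <- NA_character_
    typed
  }
  trip_start <- trip_start %||% series$time[1]
  daily <- if (nrow(typed)) daily_summaries(typed, trip_start) else NULL
  type_counts <- as.list(table(factor(typed$dive_type, levels = dive_types())))
  manifest <- list(
    package = "diveontogeny",
    version = as.character(utils::packageVersion("diveontogeny")),
    individual_id = series$individual_id,
    params = unclass(params),
    n_samples_in = n_raw,
    n_samples_analysed = length(corrected$depth),
    n_dives_detected = nrow(dives),
    n_dives_classified = nrow(typed),
    n_by_type = type_counts,
    n_days = if (is.null(daily)) 0L else nrow(daily),
    has_track = !is.null(track))
  stopifnot(manifest$n_dives_detected == manifest$n_dives_classified,
            sum(unlist(type_counts)) == nrow(typed))
  out <- structure(list(series = corrected, dives = typed, daily = daily,
                        manifest = manifest),
                   class = "dive_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_typed_dives(typed, file.path(out_dir, "dives.csv"), params)
    if (!is.null(daily)) {
      write_daily_summaries(daily, file.path(out_dir, "daily.csv"), params)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  out
}

#' @export
print.dive_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<dive_pipeline> id=%s  %d dives (%s)  %d days\n",
              m$individual_id, m$n_dives_detected,
              paste(sprintf("%s=%s", names(m$n_by_type), unlist(m$n_by_type)),
                    collapse = ", "),
              m$n_days))
  invisible(x)
}
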