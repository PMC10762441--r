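# NOAA low-order solar position equations: fractional year, equation of time
# (minutes) and solar declination (radians).
noaa_sun <- function(doy, hour_utc) {
  g <- 2 * pi / 365 * (doy - 1 + (hour_utc - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g)
                      - 0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g)
           - 0.006758 * cos(2 * g) + 0.000907 * sin(2 * g)
           - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g))
  list(eqtime = eqtime, decl = decl)
}

#' Sunrise and sunset (NOAA solar equations)
#'
#' Computes sunrise and sunset for a calendar date and position from the NOAA
#' solar position equations (fractional year, equation of time, declination,
#' hour angle at the stated zenith). The default zenith of 90.833 degrees is
#' official sunrise/sunset including atmospheric refraction and the solar
#' semi-diameter. At high latitudes the sun may not cross the zenith at all;
#' those dates return a `POLAR_DAY` or `POLAR_NIGHT` sentinel.
#'
#' Returned minutes are UTC minutes from midnight of `date` and may be
#' negative or exceed 1440 at longitudes whose local solar day spills across
#' the UTC date boundary.
#'
#' @param date a `Date` (or string coercible to one).
#' @param lon,lat position, degrees east / north.
#' @param zenith solar zenith defining rise/set, degrees.
#' @return list with `status` (`"OK"`, `"POLAR_DAY"`, `"POLAR_NIGHT"`),
#'   `sunrise_min`, `sunset_min` (UTC minutes, NA for polar sentinels),
#'   `sunrise_utc`, `sunset_utc` (POSIXct), and `noon_min`.
#' @export
solar_times <- function(date, lon, lat, zenith = 90.833) {
  date <- as.Date(date)
  if (abs(lat) > 90) stop("latitude out of range")
  lon <- wrap_lon(lon)
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  # evaluate the sun near local solar noon for this longitude
  s <- noaa_sun(doy, 12 - lon / 15)
  noon <- 720 - 4 * lon - s$eqtime
  latr <- lat * pi / 180
  cosha <- (cos(zenith * pi / 180) / (cos(latr) * cos(s$decl))
            - tan(latr) * tan(s$decl))
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  if (!is.finite(cosha) || cosha > 1) {
    return(list(status = "POLAR_NIGHT", sunrise_min = NA_real_,
                sunset_min = NA_real_, sunrise_utc = as.POSIXct(NA),
                sunset_utc = as.POSIXct(NA), noon_min = noon))
  }
  if (cosha < -1) {
    return(list(status = "POLAR_DAY", sunrise_min = NA_real_,
                sunset_min = NA_real_, sunrise_utc = as.POSIXct(NA),
                sunset_utc = as.POSIXct(NA), noon_min = noon))
  }
  ha <- acos(cosha) * 180 / pi
  rise <- noon - 4 * ha
  set <- noon + 4 * ha
  list(status = "OK", sunrise_min = rise, sunset_min = set,
       sunrise_utc = midnight + rise * 60, sunset_utc = midnight + set * 60,
       noon_min = noon)
}

#' Solar elevation angle
#'
#' Elevation of the sun (degrees above the horizon, refraction not included)
#' at a UTC time and position, from the NOAA equations via the true solar
#' time and hour angle. A time is in daylight at the standard zenith exactly
#' when `solar_elevation(...) > 90 - zenith`, i.e. above -0.833 degrees.
#'
#' @param time POSIXct (UTC), vectorized.
#' @param lon,lat position, degrees (scalars or vectors matching `time`).
#' @return numeric elevation(s), degrees.
#' @export
solar_elevation <- function(time, lon, lat) {
  lon <- wrap_lon(lon)
  doy <- as.integer(strftime(time, "%j", tz = "UTC"))
  mins <- as.numeric(time - as.POSIXct(strftime(time, "%Y-%m-%d", tz = "UTC"),
                                       tz = "UTC"), units = "mins")
  s <- noaa_sun(doy, mins / 60)
  tst <- (mins + s$eqtime + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * pi / 180
  latr <- lat * pi / 180
  cosz <- sin(latr) * sin(s$decl) + cos(latr) * cos(s$decl) * cos(ha)
  90 - acos(pmin(pmax(cosz, -1), 1)) * 180 / pi
}

#' Interpolate a sparse track to arbitrary times
#'
#' Positions between fixes are interpolated along the great circle joining
#' the bracketing fixes (so antimeridian crossings behave); times outside the
#' track's span are mapped to the nearest endpoint and flagged.
#'
#' @param track a track data frame (see [make_track()]).
#' @param times POSIXct vector.
#' @param speed_cap m/s; the track's implied fix-to-fix speeds are checked
#'   against it with a warning.
#' @return data frame with `time`, `lon`, `lat`, `extrapolated`.
#' @export
interpolate_position <- function(track, times, speed_cap = 3) {
  if (is.null(track) || !nrow(track)) stop("empty track")
  tr_t <- as.numeric(track$time)
  if (nrow(track) > 1) {
    d <- geosphere::distCosine(cbind(track$lon[-nrow(track)], track$lat[-nrow(track)]),
                               cbind(track$lon[-1], track$lat[-1]))
    sp <- d / diff(tr_t)
    if (any(sp > speed_cap)) {
      warning(sprintf("track speed exceeds %g m/s between fixes; fixes retained", speed_cap))
    }
  }
  tt <- as.numeric(times)
  lon <- lat <- numeric(length(tt))
  extra <- tt < tr_t[1] | tt > tr_t[length(tr_t)]
  i <- findInterval(tt, tr_t, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), max(nrow(track) - 1L, 1L))
  for (k in seq_along(tt)) {
    if (tt[k] <= tr_t[1]) {
      lon[k] <- track$lon[1]; lat[k] <- track$lat[1]
    } else if (tt[k] >= tr_t[nrow(track)]) {
      lon[k] <- track$lon[nrow(track)]; lat[k] <- track$lat[nrow(track)]
    } else {
      a <- i[k]; b <- a + 1L
      f <- (tt[k] - tr_t[a]) / (tr_t[b] - tr_t[a])
      p1 <- c(track$lon[a], track$lat[a]); p2 <- c(track$lon[b], track$lat[b])
      dist <- geosphere::distCosine(p1, p2)
      if (dist < 1e-6) {
        lon[k] <- p1[1]; lat[k] <- p1[2]
      } else {
        p <- geosphere::destPoint(p1, geosphere::bearing(p1, p2), f * dist)[1, ]
        lon[k] <- p[1]; lat[k] <- p[2]
      }
    }
  }
  data.frame(time = times, lon = wrap_lon(lon), lat = lat, extrapolated = extra)
}

#' Assign day or night to each dive
#'
#' Interpolates the animal's position at each dive's start time and labels
#' the dive `"day"` when the sun is above the sunrise/sunset zenith there
#' (equivalently, when the start time falls between that date's sunrise and
#' sunset), `"night"` otherwise. Polar day and polar night fall out naturally
#' from the elevation test. Dives are decided by their start time.
#'
#' @param typed a dive table with `start_time` (typically from
#'   [classify_dives()]).
#' @param track a track data frame, or `NULL` (all labels `NA`, with a
#'   warning, so the dives drop out of day/night statistics).
#' @param zenith degrees; default official sunrise/sunset.
#' @param speed_cap m/s, for track validation.
#' @return `typed` with columns `lon`, `lat`, `day_night` added.
#' @export
assign_day_night <- function(typed, track, zenith = 90.833, speed_cap = 3) {
  if (is.null(track)) {
    warning("no track: day/night labels unavailable")
    typed$lon <- NA_real_; typed$lat <- NA_real_
    typed$day_night <- NA_character_
    return(typed)
  }
  pos <- interpolate_position(track, typed$start_time, speed_cap = speed_cap)
  elev <- solar_elevation(typed$start_time, pos$lon, pos$lat)
  typed$lon <- pos$lon
  typed$lat <- pos$lat
  typed$day_night <- ifelse(elev > 90 - zenith, "day", "night")
  typed
}
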