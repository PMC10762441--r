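#' Specification of one synthetic dive
#'
#' Describes a single dive from one of the four behavioural archetypes:
#' `active_bottom` (wiggle-rich bottom phase, putative prey pursuit), `drift`
#' (a long passive segment at constant signed vertical speed), `benthic`
#' (flat, square-cornered bottom tracking the seafloor) and `transit`
#' (V-shaped travelling dive).
#'
#' Depth is positive downward. Drift rate follows the buoyancy convention:
#' vertical speed w = -d(depth)/dt, so positive drift rate means the animal
#' floats upward (positively buoyant, lipid-rich) and negative means it sinks.
#'
#' @param dive_type one of `"active_bottom"`, `"drift"`, `"benthic"`,
#'   `"transit"`.
#' @param max_depth target maximum depth, m (> 0).
#' @param duration total dive duration, s (> 0).
#' @param n_wiggles number of bottom-phase wiggles (active-bottom only).
#' @param wiggle_amplitude vertical amplitude of each wiggle, m; must be less
#'   than `max_depth / 2`.
#' @param drift_rate signed drift rate, m/s (drift only).
#' @param drift_fraction fraction of the dive spent drifting, in \[0.3, 0.8\];
#'   `drift_fraction * duration` must be at least 60 s.
#' @param descent_speed,ascent_speed maximum transit speeds, m/s. When the
#'   dive is longer than the vertical path at these speeds, descent and ascent
#'   are slowed proportionally so the pieces exactly fill the duration.
#' @param corner_smoothing time constant (s) of an exponential rounding of the
#'   benthic descent/bottom and bottom/ascent corners; 0 gives sharp corners.
#' @param leg_undulation amplitude (m/s) of a zero-mean triangular-wave
#'   modulation of the descent/ascent speed. Real dive legs undulate rather
#'   than hold a perfectly constant rate; without this, a noise-free V-dive
#'   has literally constant vertical speed on each leg and would read as
#'   "drifting". Must be smaller than both transit speeds; 0 gives exactly
#'   linear legs.
#' @return list of class `"dive_spec"`.
#' @export
dive_spec <- function(dive_type, max_depth, duration,
                      n_wiggles = 0, wiggle_amplitude = 0,
                      drift_rate = NA_real_, drift_fraction = 0.6,
                      descent_speed = 1.5, ascent_speed = 1.5,
                      corner_smoothing = 0, leg_undulation = 0) {
  dive_type <- match.arg(dive_type, dive_types())
  stopifnot(max_depth > 0, duration > 0,
            descent_speed > 0, ascent_speed > 0, corner_smoothing >= 0,
            leg_undulation >= 0)
  if (leg_undulation >= min(descent_speed, ascent_speed)) {
    stop("leg_undulation must be smaller than the transit speeds")
  }
  if (wiggle_amplitude >= max_depth / 2) {
    stop("wiggle_amplitude must be less than max_depth / 2")
  }
  if (dive_type == "active_bottom") {
    if (n_wiggles < 1) stop("active_bottom dives need n_wiggles >= 1")
    if (wiggle_amplitude <= 0) stop("active_bottom dives need wiggle_amplitude > 0")
  }
  if (dive_type == "drift") {
    if (!is.finite(drift_rate)) stop("drift dives need a finite drift_rate")
    if (drift_fraction < 0.3 || drift_fraction > 0.8) {
      stop("drift_fraction must lie in [0.3, 0.8]")
    }
    if (drift_fraction * duration < 60) {
      stop("drift segment (drift_fraction * duration) must be at least 60 s")
    }
    if (abs(drift_rate) * drift_fraction * duration > 0.75 * max_depth) {
      stop("drift segment spans more than 75% of max_depth; reduce drift_rate or drift_fraction")
    }
  }
  # descent/ascent feasibility at the stated (maximum) speeds
  tmin <- if (dive_type == "drift") {
    fd <- drift_fraction * duration
    drop <- abs(drift_rate) * fd
    dstart <- if (drift_rate <= 0) max_depth - drop else max_depth
    dend <- if (drift_rate <= 0) max_depth else max_depth - drop
    dstart / descent_speed + dend / ascent_speed + fd
  } else {
    max_depth / descent_speed + max_depth / ascent_speed
  }
  if (tmin > duration + 1e-9) {
    stop(sprintf("speeds cannot achieve max_depth within duration (need >= %.1f s)", tmin))
  }
  structure(list(dive_type = dive_type, max_depth = max_depth,
                 duration = duration, n_wiggles = n_wiggles,
                 wiggle_amplitude = wiggle_amplitude, drift_rate = drift_rate,
                 drift_fraction = drift_fraction,
                 descent_speed = descent_speed, ascent_speed = ascent_speed,
                 corner_smoothing = corner_smoothing,
                 leg_undulation = leg_undulation),
            class = "dive_spec")
}

#' The four dive-type labels
#' @return character vector of labels in canonical order.
#' @export
dive_types <- function() c("active_bottom", "drift", "benthic", "transit")

#' Generate a noise-free depth profile for one dive
#'
#' Realizes a [dive_spec()] as a piecewise profile sampled every `dt` seconds:
#' linear descent, an archetype-specific bottom phase (sinusoidal wiggles, a
#' constant-rate passive drift segment, a flat benthic shelf with optionally
#' rounded corners, or a brief/absent transit bottom), and linear ascent.
#' The first and last samples are at the surface and the achieved maximum
#' depth is within one sample interval of the target.
#'
#' @param spec a [dive_spec()].
#' @param dt sampling interval, s (> 0). The duration is rounded to a multiple
#'   of `dt`.
#' @return numeric vector of depths (m, positive down) at `0, dt, 2 dt, ...`.
#' @examples
#' d <- generate_dive_profile(dive_spec("transit", 100, 300,
#'                            descent_speed = 2/3, ascent_speed = 2/3), dt = 4)
#' length(d)  # 76 samples
#' max(d)     # within ~1.3 m of 100
#' @export
generate_dive_profile <- function(spec, dt = 4) {
  if (!inherits(spec, "dive_spec")) stop("spec must be a dive_spec")
  if (dt <= 0) stop("dt must be positive")
  dur <- round(spec$duration / dt) * dt
  if (dur < 2 * dt) stop("duration too short for the sampling interval")
  D <- spec$max_depth
  t <- seq(0, dur, by = dt)

  if (spec$dive_type == "drift") {
    fd <- spec$drift_fraction * spec$duration
    drop <- abs(spec$drift_rate) * fd
    if (spec$drift_rate <= 0) {    # sinking: drift ends at max depth
      dstart <- D - drop; dend <- D
    } else {                       # floating: drift begins at max depth
      dstart <- D; dend <- D - drop
    }
    trans <- dur - fd
    share <- (dstart / spec$descent_speed) /
      (dstart / spec$descent_speed + dend / spec$ascent_speed)
    t1 <- trans * share
    t2 <- t1 + fd
    depth <- ifelse(t <= t1, t * (dstart / t1),
             ifelse(t <= t2, dstart + (if (spec$drift_rate <= 0) 1 else -1) *
                               abs(spec$drift_rate) * (t - t1),
                    dend * (dur - t) / (dur - t2)))
    depth <- apply_undulation(depth, t, t1, t2, dur, spec$leg_undulation)
    return(finish_profile(depth))
  }

  tb <- dur - D / spec$descent_speed - D / spec$ascent_speed
  if (spec$dive_type == "transit") tb <- max(0, min(tb, 2 * dt))
  if (spec$dive_type %in% c("active_bottom", "benthic") && tb < 3 * dt) {
    stop("bottom phase too short for this archetype; increase duration or speeds")
  }
  trans <- dur - tb
  share <- (1 / spec$descent_speed) / (1 / spec$descent_speed + 1 / spec$ascent_speed)
  t1 <- trans * share        # end of descent
  t2 <- t1 + tb              # start of ascent
  vd <- D / t1; va <- D / (dur - t2)

  bottom_depth <- switch(spec$dive_type,
    transit = rep(D, sum(t > t1 & t < t2)),
    benthic = rep(D, sum(t > t1 & t < t2)),
    active_bottom = {
      u <- (t[t > t1 & t < t2] - t1) / tb
      D - spec$wiggle_amplitude / 2 +
        (spec$wiggle_amplitude / 2) * cos(2 * pi * spec$n_wiggles * u)
    })
  depth <- numeric(length(t))
  depth[t <= t1] <- t[t <= t1] * vd
  depth[t > t1 & t < t2] <- bottom_depth
  depth[t >= t2] <- (dur - t[t >= t2]) * va

  if (spec$dive_type == "benthic" && spec$corner_smoothing > 0) {
    w <- spec$corner_smoothing
    if (tb <= 2.5 * w) stop("bottom phase too short for the requested corner_smoothing")
    # C1 exponential rounding of each corner, tangent to descent/ascent lines
    ts <- t1 - w; te <- t2 + w
    cd <- ifelse(t <= ts, t * vd, D - vd * w * exp(-(t - ts) / w))
    ca <- ifelse(t >= te, (dur - t) * va, D - va * w * exp((t - te) / w))
    depth <- pmin(cd, ca)
  }
  depth <- apply_undulation(depth, t, t1, t2, dur, spec$leg_undulation)
  finish_profile(depth)
}

# Zero-mean triangular-wave speed modulation of the descent ([0, t1]) and
# ascent ([t2, dur]) legs, integrated to a depth deviation. A whole number of
# ~90 s periods fits each leg, so the deviation vanishes at both leg ends and
# the dive's endpoints and maximum depth are preserved.
apply_undulation <- function(depth, t, t1, t2, dur, a) {
  if (a <= 0) return(depth)
  tri_int <- function(u) ifelse(u < 0.5, 2 * u^2 - u, 3 * u - 2 * u^2 - 1)
  leg <- function(idx, start, len) {
    if (len < 30 || !length(idx)) return(NULL)
    P <- len / max(1, round(len / 90))
    u <- ((t[idx] - start) / P) %% 1
    a * P * tri_int(u)
  }
  i1 <- which(t > 0 & t < t1)
  dev1 <- leg(i1, 0, t1)
  if (!is.null(dev1)) depth[i1] <- depth[i1] + dev1
  i2 <- which(t > t2 & t < dur)
  dev2 <- leg(i2, t2, dur - t2)
  if (!is.null(dev2)) depth[i2] <- depth[i2] + dev2
  depth
}

finish_profile <- function(depth) {
  depth <- pmax(depth, 0)
  depth[1] <- 0
  depth[length(depth)] <- 0
  depth
}

#' Default developmental trajectories
#'
#' Smooth day-since-departure curves emulating the first migration of a
#' juvenile elephant seal: dive depth rising from ~80 m to ~400 m and duration
#' from ~5.5 min to ~20 min over the trip, and a drift-rate (buoyancy) curve
#' that starts positive (lipid-rich at departure), crosses neutral buoyancy
#' around day 10, bottoms out near -0.35 m/s, and crosses neutral buoyancy
#' again around day 125 on the way back up.
#'
#' @param day numeric vector of days since departure.
#' @return numeric vector (m, s, or m/s respectively).
#' @export
default_depth_trajectory <- function(day) 80 + 320 * (1 - exp(-day / 60))

#' @rdname default_depth_trajectory
#' @export
default_duration_trajectory <- function(day) 330 + 870 * (1 - exp(-day / 80))

#' @rdname default_depth_trajectory
#' @export
default_drift_trajectory <- function(day) {
  stats::approx(x = c(0, 10, 20, 50, 90, 125, 138, 365),
                y = c(0.20, 0, -0.20, -0.35, -0.35, 0, 0.13, 0.15),
                xout = pmax(day, 0), rule = 2)$y
}

#' Synthetic trip configuration
#'
#' Parameters of the synthetic trip generator. The defaults emulate the study
#' system: 4 s depth sampling, a dive-type mix matching the observed cohort
#' proportions (transit 44.7%, active-bottom 29.5%, benthic 16.6%, drift
#' 9.1%), developmental depth/duration increases, a buoyancy trajectory
#' crossing neutral twice (days ~10 and ~125), surface intervals of 120 +/-
#' 30 s, and a 1 m/s hourly track starting at the Ano Nuevo colony.
#'
#' @param n_days trip length in days (>= 1).
#' @param dives_per_day dives generated per day (the rest of each day is
#'   surface time).
#' @param dt sampling interval, s; must divide 86400.
#' @param depth_trajectory,duration_trajectory,drift_rate_trajectory functions
#'   of day-since-departure giving the day's target maximum depth (m), dive
#'   duration (s) and true drift rate (m/s).
#' @param type_mix named probabilities over [dive_types()]; must sum to 1.
#' @param depth_jitter_cv,duration_jitter_cv lognormal coefficient of
#'   variation applied per dive around the day's target.
#' @param drift_rate_jitter_sd per-dive Gaussian jitter on the day's drift
#'   rate, m/s.
#' @param surface_mean,surface_sd surface-interval model, s (jittered normal,
#'   floored at 40 s).
#' @param noise_sd depth measurement noise, m (Gaussian, per sample).
#' @param offset_constant constant sensor depth offset, m.
#' @param offset_walk_sd per-sample step of a slow random-walk sensor offset,
#'   m; the walk is clipped to +/- 5 m. 0 disables it.
#' @param seed integer RNG seed; the generator is bit-reproducible.
#' @param start_location `c(lon, lat)` of departure.
#' @param track_speed mean travel speed of the synthetic track, m/s (<= 3).
#' @param start_time POSIXct departure time (UTC).
#' @param individual_id id given to the synthetic animal.
#' @return list of class `"trip_config"`.
#' @export
trip_config <- function(n_days = 150, dives_per_day = 30, dt = 4,
                        depth_trajectory = default_depth_trajectory,
                        duration_trajectory = default_duration_trajectory,
                        drift_rate_trajectory = default_drift_trajectory,
                        type_mix = c(transit = 0.447, active_bottom = 0.295,
                                     benthic = 0.166, drift = 0.091),
                        depth_jitter_cv = 0.15, duration_jitter_cv = 0.12,
                        drift_rate_jitter_sd = 0.02,
                        surface_mean = 120, surface_sd = 30,
                        noise_sd = 0.3, offset_constant = 0,
                        offset_walk_sd = 0, seed = 1,
                        start_location = c(lon = -122.3, lat = 37.1),
                        track_speed = 1.0,
                        start_time = as.POSIXct("2018-05-01 00:00:00", tz = "UTC"),
                        individual_id = "sim01") {
  if (n_days <= 0) stop("n_days must be positive")
  if (dt <= 0 || (86400 %% dt) != 0) stop("dt must be positive and divide 86400")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (track_speed > 3) stop("track_speed must be <= 3 m/s")
  if (is.null(names(type_mix)) || !setequal(names(type_mix), dive_types())) {
    stop("type_mix must be named with the four dive types")
  }
  if (abs(sum(type_mix) - 1) > 0.01) stop("type_mix must sum to 1")
  type_mix <- type_mix / sum(type_mix)
  structure(as.list(environment()), class = "trip_config")
}

#' Generate a labelled synthetic trip
#'
#' Concatenates per-dive profiles with surface intervals into a regular
#' time-depth record, adds optional sensor offset (constant plus clipped
#' random walk) and Gaussian depth noise, generates an hourly great-circle
#' track, and returns ground-truth labels for every dive. Deterministic under
#' the configuration seed; the caller's RNG state is untouched.
#'
#' @param config a [trip_config()].
#' @return list of class `"sim_trip"` with elements `series` (a
#'   [tdr_series()] of the recorded i.e. offset+noise depths), `track`,
#'   `truth` (one row per dive: `dive_id`, `start_time`, `end_time`,
#'   `dive_type`, `max_depth`, `duration`, `drift_rate`, `day`), `config`,
#'   `true_depth` and `offset` (per-sample vectors).
#' @export
generate_trip <- function(config) {
  if (!inherits(config, "trip_config")) stop("config must be a trip_config")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  dt <- config$dt
  n_day_samp <- 86400 / dt
  n <- config$n_days * n_day_samp
  depth <- numeric(n)
  truth <- vector("list", config$n_days * config$dives_per_day)
  k <- 0L

  for (day in 0:(config$n_days - 1)) {
    cursor <- day * 86400
    day_end <- (day + 1) * 86400
    for (j in seq_len(config$dives_per_day)) {
      surf <- round(max(40, stats::rnorm(1, config$surface_mean, config$surface_sd)) / dt) * dt
      spec <- draw_dive_spec(config, day)
      dur <- round(spec$duration / dt) * dt
      if (cursor + surf + dur >= day_end - 2 * dt) {
        warning(sprintf("day %d full after %d dives; reduce dives_per_day or durations",
                        day, j - 1L))
        break
      }
      cursor <- cursor + surf
      prof <- generate_dive_profile(spec, dt)
      i0 <- cursor / dt + 1L
      depth[i0:(i0 + length(prof) - 1L)] <- prof
      k <- k + 1L
      truth[[k]] <- data.frame(
        dive_id = k,
        start_time = config$start_time + cursor,
        end_time = config$start_time + cursor + (length(prof) - 1L) * dt,
        dive_type = spec$dive_type,
        max_depth = spec$max_depth,
        duration = (length(prof) - 1L) * dt,
        drift_rate = if (spec$dive_type == "drift") spec$drift_rate else NA_real_,
        day = day)
      cursor <- cursor + (length(prof) - 1L) * dt
    }
  }
  truth <- do.call(rbind, truth[seq_len(k)])

  noise <- stats::rnorm(n, 0, config$noise_sd)
  offset <- rep(config$offset_constant, n)
  if (config$offset_walk_sd > 0) {
    walk <- cumsum(stats::rnorm(n, 0, config$offset_walk_sd))
    offset <- offset + pmin(pmax(walk, -5), 5)
  }
  raw <- depth + offset + noise
  times <- config$start_time + seq(0, by = dt, length.out = n)
  series <- tdr_series(config$individual_id, times, raw, dt = dt)

  track <- simulate_track(config)

  structure(list(series = series, track = track, truth = truth,
                 config = config, true_depth = depth, offset = offset),
            class = "sim_trip")
}

draw_dive_spec <- function(config, day) {
  ty <- sample(dive_types(), 1, prob = config$type_mix[dive_types()])
  D <- config$depth_trajectory(day) * exp(stats::rnorm(1, 0, config$depth_jitter_cv))
  D <- min(max(D, 20), 1500)
  dur <- config$duration_trajectory(day) * exp(stats::rnorm(1, 0, config$duration_jitter_cv))
  dur <- min(max(dur, 150), 2400)
  v <- 1.5
  und <- 0.35
  switch(ty,
    transit = {
      vt <- min(max(2 * D / dur, 0.9), 2.2)
      dur_t <- (round(2 * D / vt / config$dt) + 2) * config$dt
      dive_spec("transit", D, dur_t,
                descent_speed = 1.02 * 2 * D / dur_t,
                ascent_speed = 1.02 * 2 * D / dur_t,
                leg_undulation = und * 2 * D / dur_t)
    },
    active_bottom = {
      dur_a <- max(dur, 2 * D / v + 200)
      tb <- dur_a - 2 * D / v
      A <- (0.10 + 0.07 * stats::runif(1)) * D
      # keep peak wiggle speed (pi k A / tb) inside [0.8, 1.8] m/s
      kmin <- max(5, ceiling(0.8 * tb / (pi * A)))
      kmax <- max(kmin, floor(1.8 * tb / (pi * A)))
      ks <- kmin:min(kmax, kmin + 5)
      k <- ks[sample.int(length(ks), 1)]
      dive_spec("active_bottom", D, dur_a, n_wiggles = k, wiggle_amplitude = A,
                descent_speed = v, ascent_speed = v, leg_undulation = und * v)
    },
    benthic = {
      dur_b <- max(dur, 2 * D / v + 150)
      dive_spec("benthic", D, dur_b, descent_speed = v, ascent_speed = v,
                leg_undulation = und * v)
    },
    drift = {
      rate <- config$drift_rate_trajectory(day) +
        stats::rnorm(1, 0, config$drift_rate_jitter_sd)
      f <- stats::runif(1, 0.5, 0.75)
      g <- f / (1 - f)
      # closed-form drift duration: fd = g * transit_time(fd)
      fd <- g * 2 * D / v / (1 + g * abs(rate) / v)
      fd <- max(60, min(fd, if (abs(rate) > 1e-6) 0.6 * D / abs(rate) else Inf))
      drop <- abs(rate) * fd
      path_t <- (2 * D - drop) / v
      dur_d <- ceiling((path_t + fd) / config$dt) * config$dt
      dive_spec("drift", D, dur_d, drift_rate = rate,
                drift_fraction = fd / dur_d,
                descent_speed = v, ascent_speed = v, leg_undulation = und * v)
    })
}

simulate_track <- function(config) {
  n_fix <- config$n_days * 24 + 1
  heading <- (stats::runif(1, 0, 360) +
                cumsum(c(0, stats::rnorm(n_fix - 1, 0, 8)))) %% 360
  step <- config$track_speed * 3600 * stats::runif(n_fix - 1, 0.5, 0.9)
  pos <- matrix(NA_real_, n_fix, 2)
  pos[1, ] <- c(wrap_lon(config$start_location[["lon"]]),
                config$start_location[["lat"]])
  for (i in 2:n_fix) {
    pos[i, ] <- geosphere::destPoint(pos[i - 1, ], heading[i - 1], step[i - 1])[1, ]
  }
  make_track(config$start_time + (seq_len(n_fix) - 1) * 3600,
             wrap_lon(pos[, 1]), pmin(pmax(pos[, 2], -89.9), 89.9),
             speed_cap = 3)
}

#' @export
print.sim_trip <- function(x, ...) {
  cat(sprintf("<sim_trip> %d days, %d dives (%s), %d samples at %gs\n",
              x$config$n_days, nrow(x$truth),
              paste(sprintf("%s=%d", names(table(x$truth$dive_type)),
                            as.integer(table(x$truth$dive_type))), collapse = ", "),
              length(x$series$depth), x$series$dt))
  invisible(x)
}

#' Write a synthetic trip to CSV files
#'
#' Writes `tdr.csv` (individual_id, timestamp_utc, depth_m), `track.csv`
#' (timestamp_utc, lon, lat) and `truth.csv` (dive_start, dive_type,
#' drift_rate, max_depth, duration) under `dir`.
#'
#' @param sim a [generate_trip()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_trip <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tdr(sim$series, file.path(dir, "tdr.csv"))
  write_track(sim$track, file.path(dir, "track.csv"))
  tr <- data.frame(dive_start = sim$truth$start_time,
                   dive_type = sim$truth$dive_type,
                   drift_rate = sim$truth$drift_rate,
                   max_depth = sim$truth$max_depth,
                   duration = sim$truth$duration)
  write_csv_with_header(tr, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Match detected dives to generator truth
#'
#' A detected dive matches a truth dive when it contains the truth dive's
#' midpoint. Returns, for each truth row, the row index of the matching
#' detected dive (NA when undetected).
#'
#' @param truth the `truth` data frame of a [generate_trip()] result.
#' @param dives a detected dive table (see [detect_dives()]).
#' @return integer vector of length `nrow(truth)`.
#' @export
match_truth <- function(truth, dives) {
  mid <- as.numeric(truth$start_time) +
    (as.numeric(truth$end_time) - as.numeric(truth$start_time)) / 2
  s <- as.numeric(dives$start_time); e <- as.numeric(dives$end_time)
  vapply(mid, function(m) {
    i <- which(s <= m & e >= m)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
}
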