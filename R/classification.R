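#' Bottom-phase intensity index
#'
#' Activity score of a dive's bottom phase, built from the wiggle count `W`,
#' the total bottom vertical distance `V` (m), the bottom depth range `R` (m)
#' and the bottom duration `T` (s):
#'
#' \deqn{I = \frac{W V}{R}\left(1 + \frac{V}{T}\right)}
#'
#' Many wiggles covering much vertical distance relative to the depth range,
#' at a high vertical rate, mark putative prey pursuit. A flat or wiggle-free
#' bottom (`W = 0` or `R = 0`) scores 0 by definition. Dives scoring strictly
#' above the threshold (35 by default) are active-bottom dives.
#'
#' @param W,V,R,T bottom-phase metrics (vectorized); see [bottom_metrics()].
#' @return numeric score(s), dimensionless.
#' @examples
#' intensity_index(5, 100, 20, 600)   # 29.17, below 35
#' intensity_index(8, 240, 30, 600)   # 89.6, above 35
#' @export
intensity_index <- function(W, V, R, T) {
  ifelse(W <= 0 | R <= 0 | T <= 0, 0, (W * V / R) * (1 + V / T))
}

#' Active-bottom test
#'
#' @param metrics list or data frame with `W`, `V`, `R`, `T`.
#' @param threshold intensity cut; the comparison is strict (`>`).
#' @return logical.
#' @export
classify_active_bottom <- function(metrics, threshold = 35) {
  intensity_index(metrics$W, metrics$V, metrics$R, metrics$T) > threshold
}

#' Vertical speed of a depth profile
#'
#' First derivative of the time-depth profile with the buoyancy sign
#' convention: `w[i] = -(depth[i+1] - depth[i]) / dt`, so positive speeds
#' point upward and a positively buoyant drifting animal has positive drift
#' rate.
#'
#' @param depths numeric depths, m (positive down).
#' @param dt sampling interval, s.
#' @return numeric vector of length `length(depths) - 1`, m/s.
#' @export
vertical_speed <- function(depths, dt) {
  if (length(depths) < 2) stop("need at least 2 samples")
  -diff(depths) / dt
}

#' Kernel density peak of a vertical-speed sample
#'
#' Gaussian kernel density of the speeds evaluated on a fixed grid
#' (default -2.5 to 2.5 m/s in 0.005 m/s steps), returning the location and
#' height of the global maximum. The peak location is the dominant
#' (modal) vertical speed; its height measures how much of the dive was spent
#' at that speed. Bandwidth is Silverman's rule on the dive's own speeds
#' unless a fixed bandwidth is supplied; a floor of 0.01 m/s keeps the
#' density defined for constant samples.
#'
#' @param speeds numeric vertical speeds, m/s.
#' @param bw fixed bandwidth (m/s) or `NULL` for Silverman's rule.
#' @param grid_min,grid_max,grid_step evaluation grid, m/s.
#' @param min_n minimum sample size; below it a no-peak sentinel
#'   (`location = height = NA`) is returned.
#' @return list with `location` (m/s), `height` (s/m), `bw`, `n`, and
#'   `integral` (trapezoidal mass of the density over the grid).
#' @export
drift_kde <- function(speeds, bw = NULL, grid_min = -2.5, grid_max = 2.5,
                      grid_step = 0.005, min_n = 10) {
  speeds <- speeds[is.finite(speeds)]
  n <- length(speeds)
  if (n < min_n) {
    return(list(location = NA_real_, height = NA_real_, bw = NA_real_,
                n = n, integral = NA_real_))
  }
  if (is.null(bw)) {
    bw <- tryCatch(stats::bw.nrd0(speeds), error = function(e) 0.01)
    if (!is.finite(bw) || bw < 0.01) bw <- 0.01
  }
  ngrid <- round((grid_max - grid_min) / grid_step) + 1L
  den <- stats::density(speeds, bw = bw, from = grid_min, to = grid_max,
                        n = ngrid)
  i <- which.max(den$y)
  list(location = den$x[i], height = den$y[i], bw = bw, n = n,
       integral = sum((den$y[-1] + den$y[-ngrid]) / 2) * grid_step)
}

#' Drift-dive test
#'
#' A dive whose whole-dive vertical-speed density has a peak higher than the
#' density threshold (1 by default, strict) spent a large fraction of its time
#' at one vertical speed and is called a drift dive; the peak location is the
#' dive's drift rate.
#'
#' @param peak a [drift_kde()] result.
#' @param height_threshold density threshold (s/m).
#' @return list with `is_drift` and `drift_rate` (NA unless `is_drift`).
#' @export
classify_drift <- function(peak, height_threshold = 1) {
  ok <- is.finite(peak$height) && peak$height > height_threshold
  list(is_drift = ok, drift_rate = if (ok) peak$location else NA_real_)
}

#' Benthic-dive test
#'
#' Two detectors, combined by conjunction by default: (i) the bottom-phase
#' vertical-speed density peak lies within +/- `speed_window` of zero (nearly
#' flat bottom) with height above `density_threshold` (consistent speed); and
#' (ii) a square-corner test: least-squares lines are fitted to depth versus
#' time over the descent span and the bottom span, and the observed depth at
#' their intersection time must lie within `corner_tolerance` metres
#' (strictly) of the intersection depth. Near-parallel lines (slope
#' difference below 1e-6 m/s) fail the corner test.
#'
#' @param depths the dive's depth samples.
#' @param seg a [segment_phases()] result.
#' @param dt sampling interval, s.
#' @param params a [dive_params()].
#' @return list with `is_benthic`, `kde_pass`, `corner_pass`, and the bottom
#'   peak (`bottom_location`, `bottom_height`).
#' @export
classify_benthic <- function(depths, seg, dt, params = dive_params()) {
  fail <- list(is_benthic = FALSE, kde_pass = FALSE, corner_pass = FALSE,
               bottom_location = NA_real_, bottom_height = NA_real_)
  b <- seg$bottom
  if (is.null(b) || (b[2] - b[1] + 1L) < 5L) return(fail)
  bs <- vertical_speed(depths[b[1]:b[2]], dt)
  pk <- drift_kde(bs, bw = params$kde_bandwidth,
                  grid_min = params$kde_grid_min, grid_max = params$kde_grid_max,
                  grid_step = params$kde_grid_step, min_n = 4)
  kde_pass <- is.finite(pk$height) &&
    abs(pk$location) <= params$benthic_speed_window &&
    pk$height > params$benthic_density_threshold
  corner_pass <- corner_test(depths, seg, dt, params$corner_tolerance)
  ok <- if (params$benthic_rule == "disjunction") kde_pass || corner_pass
        else kde_pass && corner_pass
  list(is_benthic = ok, kde_pass = kde_pass, corner_pass = corner_pass,
       bottom_location = pk$location, bottom_height = pk$height)
}

corner_test <- function(depths, seg, dt, tolerance) {
  d <- seg$descent; b <- seg$bottom
  if (is.null(d) || (d[2] - d[1]) < 1L || (b[2] - b[1]) < 1L) return(FALSE)
  t <- (seq_along(depths) - 1) * dt
  f1 <- line_fit(t[d[1]:d[2]], depths[d[1]:d[2]])
  f2 <- line_fit(t[b[1]:b[2]], depths[b[1]:b[2]])
  if (abs(f1$slope - f2$slope) < 1e-6) return(FALSE)
  tstar <- (f2$intercept - f1$intercept) / (f1$slope - f2$slope)
  inter_depth <- f1$slope * tstar + f1$intercept
  obs <- stats::approx(t, depths, xout = tstar, rule = 2, ties = "ordered")$y
  abs(obs - inter_depth) < tolerance
}

line_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sl <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  list(slope = sl, intercept = my - sl * mx)
}

#' Classify every detected dive
#'
#' Runs the three detectors on each dive of a dive table and assigns exactly
#' one label with the precedence benthic > drift > active-bottom > transit.
#' Benthic dives often also register as drift dives because of their very
#' consistent depth rate, so the benthic label overrides the drift label;
#' dives failing all three detectors are transit dives. A drift rate is
#' attached only to drift dives.
#'
#' @param series the corrected [tdr_series()] the dives were detected in.
#' @param dives a [detect_dives()] table.
#' @param params a [dive_params()].
#' @return the dive table of class `"typed_dive_table"` augmented with:
#'   `bottom_start`, `bottom_end` (absolute sample indices), `W`, `V_m`,
#'   `R_m`, `T_s`, `intensity_index`, `kde_peak_location`, `kde_peak_height`,
#'   `kde_bw`, `benthic_kde_pass`, `benthic_corner_pass`, `dive_type`,
#'   `drift_rate_ms`, `flagged`.
#' @export
classify_dives <- function(series, dives, params = dive_params()) {
  n <- nrow(dives)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    d <- series$depth[dives$start_idx[i]:dives$end_idx[i]]
    seg <- segment_phases(d, params$bottom_fraction)
    m <- bottom_metrics(d, seg, series$dt, params$wiggle_min_amplitude)
    ii <- intensity_index(m$W, m$V, m$R, m$T)
    spd <- vertical_speed(d, series$dt)
    pk <- drift_kde(spd, bw = params$kde_bandwidth,
                    grid_min = params$kde_grid_min,
                    grid_max = params$kde_grid_max,
                    grid_step = params$kde_grid_step,
                    min_n = params$min_speed_samples)
    dr <- classify_drift(pk, params$drift_density_threshold)
    bn <- classify_benthic(d, seg, series$dt, params)
    label <- if (bn$is_benthic) "benthic"
             else if (dr$is_drift) "drift"
             else if (ii > params$intensity_threshold) "active_bottom"
             else "transit"
    res[[i]] <- data.frame(
      bottom_start = dives$start_idx[i] + seg$bottom[1] - 1L,
      bottom_end = dives$start_idx[i] + seg$bottom[2] - 1L,
      W = m$W, V_m = m$V, R_m = m$R, T_s = m$T,
      intensity_index = ii,
      kde_peak_location = pk$location, kde_peak_height = pk$height,
      kde_bw = pk$bw,
      benthic_kde_pass = bn$kde_pass, benthic_corner_pass = bn$corner_pass,
      dive_type = label,
      drift_rate_ms = if (label == "drift") dr$drift_rate else NA_real_,
      flagged = seg$flagged)
  }
  out <- cbind(as.data.frame(dives), do.call(rbind, res))
  class(out) <- c("typed_dive_table", "dive_table", "data.frame")
  out
}

#' Write a typed-dive table to CSV
#'
#' @param typed a [classify_dives()] table.
#' @param path output path.
#' @param params optional [dive_params()] serialized as a `#` comment header.
#' @return `path`, invisibly.
#' @export
write_typed_dives <- function(typed, path, params = NULL) {
  write_csv_with_header(as.data.frame(typed), path, params)
}
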