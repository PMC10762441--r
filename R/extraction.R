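#' Zero-offset correction
#'
#' Pressure transducers drift slowly, so raw "surface" readings wander away
#' from 0 m. The correction estimates the surface offset in successive time
#' blocks as a low percentile of the samples shallower than a guard depth,
#' interpolates the block estimates linearly over time, and subtracts them.
#' Corrected depths are clipped below at -2 m.
#'
#' Because a quantile is shift-equivariant, applying a constant offset to a
#' record and re-correcting reproduces the original corrected record.
#'
#' @param series a [tdr_series()] of raw depths.
#' @param window block length, s (default 6 h).
#' @param guard_depth only samples shallower than this (m) enter the surface
#'   estimate (default 15 m).
#' @param probs quantile taken as the surface reading (default 0.02).
#' @return corrected [tdr_series()]; the per-sample offset that was removed is
#'   attached as `attr(, "offset")`.
#' @export
zero_offset_correct <- function(series, window = 21600, guard_depth = 15,
                                probs = 0.02) {
  tt <- as.numeric(series$time)
  block <- floor((tt - tt[1]) / window)
  ub <- unique(block)
  centers <- offs <- numeric(length(ub))
  for (i in seq_along(ub)) {
    sel <- block == ub[i]
    centers[i] <- tt[1] + (ub[i] + 0.5) * window
    near <- series$depth[sel][series$depth[sel] < guard_depth]
    offs[i] <- if (length(near)) {
      stats::quantile(near, probs, names = FALSE, type = 7)
    } else NA_real_
  }
  if (anyNA(offs)) {
    warning("window(s) with no near-surface samples; carrying neighbouring offset")
    ok <- which(!is.na(offs))
    if (!length(ok)) stop("no near-surface samples anywhere; cannot estimate offset")
    offs <- stats::approx(centers[ok], offs[ok], xout = centers,
                          rule = 2, ties = "ordered")$y
  }
  off_t <- if (length(ub) == 1L) rep(offs, length(tt)) else {
    stats::approx(centers, offs, xout = tt, rule = 2, ties = "ordered")$y
  }
  out <- tdr_series(series$individual_id, series$time,
                    pmax(series$depth - off_t, -2), dt = series$dt)
  attr(out, "offset") <- off_t
  out
}

#' Detect dives in a corrected series
#'
#' A dive is a maximal excursion below the surface threshold whose maximum
#' depth reaches `min_depth` and whose surface-to-surface duration reaches
#' `min_duration`. The default 10 m / 30 s criterion suits 4 s archival
#' records; `dive_params(preset = "dsa_complete_dive")` gives the 15 m / 60 s
#' complete-dive criterion of satellite-relay tags. The series should be
#' zero-offset corrected first.
#'
#' @param series a [tdr_series()] (post-correction).
#' @param min_depth,min_duration,surface_threshold thresholds (m, s, m); the
#'   defaults are taken from `params` when supplied.
#' @param params optional [dive_params()] supplying the thresholds.
#' @return data frame of class `"dive_table"`, one row per dive, ordered and
#'   non-overlapping: `dive_id`, `start_idx`, `end_idx` (sample indices into
#'   the series, inclusive; the bounding surface samples), `start_time`,
#'   `end_time`, `duration`, `max_depth`, `n_samples`.
#' @export
detect_dives <- function(series, min_depth = params$min_depth,
                         min_duration = params$min_duration,
                         surface_threshold = params$surface_threshold,
                         params = dive_params()) {
  under <- series$depth > surface_threshold
  r <- rle(under)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  wet <- which(r$values)
  if (!length(wet)) return(empty_dive_table())
  n <- length(series$depth)
  s <- pmax(starts[wet] - 1L, 1L)   # bounding surface sample before
  e <- pmin(ends[wet] + 1L, n)      # bounding surface sample after
  tt <- as.numeric(series$time)
  dur <- tt[e] - tt[s]
  maxd <- vapply(seq_along(s), function(i) max(series$depth[s[i]:e[i]]), numeric(1))
  keep <- maxd >= min_depth & dur >= min_duration
  out <- data.frame(dive_id = seq_len(sum(keep)),
                    start_idx = s[keep], end_idx = e[keep],
                    start_time = series$time[s[keep]],
                    end_time = series$time[e[keep]],
                    duration = dur[keep], max_depth = maxd[keep],
                    n_samples = e[keep] - s[keep] + 1L)
  class(out) <- c("dive_table", "data.frame")
  out
}

empty_dive_table <- function() {
  out <- data.frame(dive_id = integer(), start_idx = integer(),
                    end_idx = integer(),
                    start_time = as.POSIXct(character(), tz = "UTC"),
                    end_time = as.POSIXct(character(), tz = "UTC"),
                    duration = numeric(), max_depth = numeric(),
                    n_samples = integer())
  class(out) <- c("dive_table", "data.frame")
  out
}

#' Segment a dive into descent, bottom and ascent
#'
#' The bottom phase runs from the first to the last sample at or below
#' `bottom_fraction` of the dive's maximum depth (default 80%, the standard
#' TDR convention); descent is everything before, ascent everything after.
#' Dives with fewer than 8 samples, or degenerate records with no ascent or
#' no descent, are flagged and treated as all-bottom where needed.
#'
#' @param depths the dive's depth samples (surface to surface).
#' @param bottom_fraction fraction of maximum depth defining the bottom.
#' @return list with integer spans (local indices, inclusive) `descent`,
#'   `bottom`, `ascent` (any may be `NULL`), and `flagged`.
#' @export
segment_phases <- function(depths, bottom_fraction = 0.8) {
  n <- length(depths)
  maxd <- max(depths)
  if (n < 8) {
    return(list(descent = NULL, bottom = c(1L, n), ascent = NULL, flagged = TRUE))
  }
  deep <- which(depths >= bottom_fraction * maxd)
  b1 <- deep[1]; b2 <- deep[length(deep)]
  flagged <- b1 <= 1L || b2 >= n
  list(descent = if (b1 > 1L) c(1L, b1 - 1L) else NULL,
       bottom = c(b1, b2),
       ascent = if (b2 < n) c(b2 + 1L, n) else NULL,
       flagged = flagged)
}

#' Bottom-phase activity metrics
#'
#' Computes the four quantities that feed the intensity index: `W`, the
#' number of wiggles (vertical inflections of amplitude at least
#' `wiggle_min_amplitude`); `V`, the total vertical distance travelled in the
#' bottom phase (m); `R`, the range of bottom depths (m); and `T`, the bottom
#' duration (s). Wiggles are counted on the pruned sequence of alternating
#' extrema, so measurement noise smaller than the amplitude threshold adds no
#' wiggles; `V >= R` always.
#'
#' @param depths the dive's depth samples.
#' @param seg a [segment_phases()] result for those samples.
#' @param dt sampling interval, s.
#' @param wiggle_min_amplitude minimum wiggle amplitude, m.
#' @return list with `W`, `V`, `R`, `T`.
#' @export
bottom_metrics <- function(depths, seg, dt, wiggle_min_amplitude = 2) {
  b <- depths[seg$bottom[1]:seg$bottom[2]]
  list(W = count_wiggles(b, wiggle_min_amplitude),
       V = sum(abs(diff(b))),
       R = max(b) - min(b),
       T = (length(b) - 1L) * dt)
}

# Count local depth minima (shallowing-then-deepening inflections) whose
# vertical swing is at least `amp` on both sides, by hysteresis tracking.
count_wiggles <- function(d, amp) {
  n <- length(d)
  if (n < 3L) return(0L)
  w <- 0L
  dir <- 0L            # +1 deepening, -1 shallowing, 0 undecided
  hi <- d[1]; lo <- d[1]
  for (x in d[-1]) {
    if (x > hi) hi <- x
    if (x < lo) lo <- x
    if (dir <= 0L && x - lo >= amp) {      # swing down ends a shallowing run
      if (dir == -1L) w <- w + 1L
      dir <- 1L; hi <- x
    } else if (dir >= 0L && hi - x >= amp) { # swing up starts a shallowing run
      dir <- -1L; lo <- x
    }
  }
  w
}
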