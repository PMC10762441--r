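#' Analysis parameter set
#'
#' Collects every threshold used by the processing and classification chain in
#' one place, so that a run is fully described by its parameter set and no
#' constant hides inside a code path. The defaults are the values used
#' throughout the elephant-seal dive-typing literature: dives are excursions
#' deeper than 10 m lasting at least 30 s, the bottom phase is the portion of
#' a dive below 80% of its maximum depth, a dive with intensity index above 35
#' is an active-bottom dive, a vertical-speed density peak above 1 marks a
#' drift dive, and a bottom-phase peak within +/-0.08 m/s with density above
#' 1.5 together with a corner mismatch under 15 m marks a benthic dive.
#'
#' @param preset `"standard"` for the 10 m / 30 s dive criterion applied to
#'   4 s archival records, or `"dsa_complete_dive"` for the 15 m / 60 s
#'   complete-dive criterion used by satellite-relay (DSA) tags.
#' @param ... named overrides for any parameter listed below.
#'
#' @details Parameters (units in brackets):
#' \describe{
#'   \item{min_depth \[m\], min_duration \[s\]}{dive detection thresholds.}
#'   \item{surface_threshold \[m\]}{post-correction depth below which a sample
#'     counts as "at the surface" when delimiting excursions (2 m).}
#'   \item{target_dt \[s\]}{common analysis resolution; records sampled faster
#'     are decimated to this interval (4 s).}
#'   \item{zoc_window \[s\], zoc_guard_depth \[m\], zoc_quantile}{zero-offset
#'     correction: block length (6 h), guard depth for "near-surface" samples
#'     (15 m), and the low quantile taken as the surface reading (0.02).}
#'   \item{bottom_fraction}{fraction of maximum depth defining the bottom
#'     phase (0.8).}
#'   \item{wiggle_min_amplitude \[m\]}{minimum vertical amplitude for a bottom
#'     inflection to count as a wiggle (2 m).}
#'   \item{intensity_threshold}{active-bottom cut on the intensity index (35,
#'     strict).}
#'   \item{drift_density_threshold \[s/m\]}{minimum height of the whole-dive
#'     vertical-speed density peak for a drift call (1, strict).}
#'   \item{benthic_density_threshold \[s/m\], benthic_speed_window \[m/s\]}{
#'     bottom-phase density peak height (1.5) and location window (0.08 m/s)
#'     for the benthic flat-bottom test.}
#'   \item{corner_tolerance \[m\]}{maximum vertical distance between the
#'     observed trajectory and the descent/bottom line intersection for a
#'     "square corner" (15 m, strict less-than).}
#'   \item{benthic_rule}{`"conjunction"` (default) requires the flat-bottom
#'     density test AND the corner test; `"disjunction"` accepts either.}
#'   \item{kde_bandwidth \[m/s\]}{Gaussian bandwidth for the speed densities
#'     (default fixed at 0.1 m/s, or `NULL` for Silverman's rule per dive).
#'     The density-height thresholds (1 and 1.5) only keep a consistent
#'     meaning across dives at a fixed bandwidth: a data-driven rule widens
#'     on multimodal speed samples and shrinks on drift-dominated ones, so
#'     the same dive can cross the threshold either way. The bandwidth is
#'     recorded per dive in the output.}
#'   \item{kde_grid_min, kde_grid_max, kde_grid_step \[m/s\]}{fixed evaluation
#'     grid for all speed densities (-2.5 to 2.5 by 0.005).}
#'   \item{min_speed_samples}{minimum number of speed samples for a whole-dive
#'     density (10); dives below it get no drift call.}
#'   \item{smoothing_window \[days\]}{running-median window for the daily
#'     drift-rate series before crossing detection (7).}
#'   \item{solar_zenith \[degrees\]}{zenith defining sunrise/sunset (90.833,
#'     official sunrise including refraction).}
#'   \item{speed_cap \[m/s\]}{maximum plausible travel speed used to validate
#'     tracks (3).}
#' }
#'
#' @return A named list of class `"dive_params"`.
#' @examples
#' p <- dive_params()
#' p$min_depth
#' dive_params(preset = "dsa_complete_dive")$min_duration
#' @export
dive_params <- function(preset = c("standard", "dsa_complete_dive"), ...) {
  preset <- match.arg(preset)
  p <- list(
    min_depth = 10,
    min_duration = 30,
    surface_threshold = 2,
    target_dt = 4,
    zoc_window = 21600,
    zoc_guard_depth = 15,
    zoc_quantile = 0.02,
    bottom_fraction = 0.8,
    wiggle_min_amplitude = 2,
    intensity_threshold = 35,
    drift_density_threshold = 1,
    benthic_density_threshold = 1.5,
    benthic_speed_window = 0.08,
    corner_tolerance = 15,
    benthic_rule = "conjunction",
    kde_bandwidth = 0.1,
    kde_grid_min = -2.5,
    kde_grid_max = 2.5,
    kde_grid_step = 0.005,
    min_speed_samples = 10,
    smoothing_window = 7,
    solar_zenith = 90.833,
    speed_cap = 3
  )
  if (preset == "dsa_complete_dive") {
    p$min_depth <- 15
    p$min_duration <- 60
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(over)] <- over
  }
  stopifnot(
    p$min_depth > 0, p$min_duration > 0, p$surface_threshold > 0,
    p$target_dt > 0, p$zoc_window > 0, p$zoc_guard_depth > 0,
    p$zoc_quantile > 0, p$zoc_quantile < 1,
    p$bottom_fraction > 0, p$bottom_fraction < 1,
    p$wiggle_min_amplitude > 0, p$benthic_speed_window > 0,
    p$corner_tolerance > 0, p$kde_grid_step > 0,
    p$kde_grid_max > p$kde_grid_min, p$speed_cap > 0,
    p$benthic_rule %in% c("conjunction", "disjunction")
  )
  class(p) <- "dive_params"
  p
}

#' @export
print.dive_params <- function(x, ...) {
  cat("<dive_params>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

# Serialize params as "# name: value" comment lines for CSV headers.
params_header <- function(params) {
  vapply(names(params), function(nm) {
    v <- params[[nm]]
    sprintf("# %s: %s", nm, if (is.null(v)) "NULL" else paste(format(v), collapse = " "))
  }, character(1))
}
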