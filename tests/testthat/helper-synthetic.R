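# Shared small fixtures, generated in code and cached per test run.

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_trip(trip_config(n_days = 4, dives_per_day = 12,
                                          noise_sd = 0, seed = 101))
    }
    cache
  }
})

# A hand-built series with three excursions: 9 m for ~200 s, 12 m for ~40 s,
# 50 m for ~300 s, separated by surface stretches. dt = 4 s.
three_excursion_series <- function() {
  blocks <- list(
    rep(0, 10),
    c(3, 6, 9, rep(9, 44), 6, 3),                   # 9 m, 200 s: 50 samples
    rep(0, 10),
    c(4, 8, 12, 12, 12, 12, 12, 8, 4),              # 12 m, 40 s: 9 samples
    rep(0, 10),
    c(seq(5, 50, by = 5), rep(50, 55), seq(45, 5, by = -5)),  # 50 m, 300 s
    rep(0, 10))
  depth <- unlist(blocks)
  tdr_series("fixture", seq(0, by = 4, length.out = length(depth)) +
               as.POSIXct("2020-01-01", tz = "UTC"), depth, dt = 4)
}

# Count local depth minima of a noise-free profile (independent oracle for
# the wiggle counter): sign changes of the first difference, falling -> rising.
oracle_minima <- function(d) {
  s <- sign(diff(d))
  s <- s[s != 0]
  sum(s[-1] > 0 & s[-length(s)] < 0)
}

# Oracle sunrise/sunset values (UTC minutes from midnight of the date,
# zenith 90.833) computed independently with the Meeus/Julian-century solar
# equations before the solar module was written.
solar_oracle <- data.frame(
  date = c("2018-05-01", "2014-12-01", "2020-03-20", "2015-09-15", "2019-01-15"),
  lon = c(-122.3, 70.33, 0, 170, -60),
  lat = c(37.1, -49.33, 0, -40, 55),
  rise = c(794.241, -49.597, 363.971, -318.023, 735.686),
  set = c(1618.292, 904.844, 1090.635, 389.042, 1203.061))

expect_series_equal <- function(a, b, tol = 1e-9) {
  expect_equal(as.numeric(a$time), as.numeric(b$time))
  expect_equal(a$depth, b$depth, tolerance = tol)
}
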