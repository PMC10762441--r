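test_that("transit profile realizes a V of the right size", {
  s <- dive_spec("transit", 100, 300, descent_speed = 2/3, ascent_speed = 2/3)
  d <- generate_dive_profile(s, dt = 4)
  expect_length(d, 76)
  expect_equal(d[1], 0)
  expect_equal(d[76], 0)
  expect_lt(abs(max(d) - 100), 1.34)   # apex can fall between samples
  apex <- which.max(d)
  expect_true(all(diff(d[1:apex]) > 0))
  expect_true(all(diff(d[apex:76]) <= 0))  # apex may straddle two samples
  expect_true(all(diff(d[(apex + 1):76]) < 0))
})

test_that("drift profile contains the stated constant-rate segment", {
  s <- dive_spec("drift", 350, 1000, drift_rate = -0.3, drift_fraction = 0.6)
  d <- generate_dive_profile(s, dt = 4)
  w <- vertical_speed(d, 4)
  # 600 s at -0.3 m/s = 150 consecutive speed samples
  r <- rle(abs(w + 0.3) < 1e-9)
  expect_gte(max(r$lengths[r$values]), 149)
  expect_lt(abs(max(d) - 350), 1.5)
  # positive (floating) drift rates put the drift just after the descent
  s2 <- dive_spec("drift", 350, 1000, drift_rate = 0.25, drift_fraction = 0.6)
  w2 <- vertical_speed(generate_dive_profile(s2, 4), 4)
  r2 <- rle(abs(w2 - 0.25) < 1e-9)
  expect_gte(max(r2$lengths[r2$values]), 149)
})

test_that("active-bottom profile has exactly the requested wiggle count", {
  for (k in c(3, 6, 9)) {
    s <- dive_spec("active_bottom", 200, 700, n_wiggles = k,
                   wiggle_amplitude = 8)
    d <- generate_dive_profile(s, dt = 4)
    seg <- segment_phases(d)
    b <- d[seg$bottom[1]:seg$bottom[2]]
    expect_equal(oracle_minima(b), k)
  }
})

test_that("invalid dive specs are rejected", {
  expect_error(dive_spec("transit", 400, 120), "cannot achieve")
  expect_error(dive_spec("drift", 300, 500, drift_rate = -0.3,
                         drift_fraction = 0.1), "drift_fraction")
  expect_error(dive_spec("drift", 300, 150, drift_rate = -0.3,
                         drift_fraction = 0.35), "60 s")
  expect_error(dive_spec("active_bottom", 100, 400, n_wiggles = 4,
                         wiggle_amplitude = 60), "max_depth / 2")
  expect_error(generate_dive_profile(dive_spec("benthic", 100, 500), dt = -1),
               "dt")
})

test_that("trip generation is bit-reproducible under a fixed seed", {
  cfg <- trip_config(n_days = 2, dives_per_day = 8, seed = 9)
  a <- generate_trip(cfg)
  b <- generate_trip(cfg)
  expect_identical(a$series$depth, b$series$depth)
  expect_identical(a$truth, b$truth)
  expect_identical(a$track$lon, b$track$lon)
})

test_that("generate_trip leaves the caller's RNG state alone", {
  set.seed(123)
  u1 <- runif(1)
  set.seed(123)
  invisible(generate_trip(trip_config(n_days = 1, dives_per_day = 3, seed = 77)))
  expect_identical(runif(1), u1)
})

test_that("truth labels align with the configured buoyancy trajectory", {
  sim <- small_sim()
  early <- sim$truth[sim$truth$day <= 3 & sim$truth$dive_type == "drift", ]
  expect_true(all(early$drift_rate > 0))  # before the day-10 crossing
  expect_true(all(diff(as.numeric(sim$series$time)) == sim$config$dt))
  # every truth dive corresponds to a depth excursion
  for (i in seq_len(nrow(sim$truth))) {
    i0 <- which(sim$series$time == sim$truth$start_time[i])
    i1 <- which(sim$series$time == sim$truth$end_time[i])
    expect_lt(abs(max(sim$series$depth[i0:i1]) - sim$truth$max_depth[i]), 2)
  }
})

test_that("benthic bottom phases satisfy the flat-bottom criteria when re-measured", {
  sim <- small_sim()
  srs <- sim$series
  p <- dive_params()
  dives <- detect_dives(srs, params = p)
  mt <- match_truth(sim$truth, dives)
  ben <- which(sim$truth$dive_type == "benthic")
  for (i in ben) {
    d <- srs$depth[dives$start_idx[mt[i]]:dives$end_idx[mt[i]]]
    seg <- segment_phases(d, p$bottom_fraction)
    # the flat shelf itself (the deepest samples) has near-zero vertical speed;
    # the 80%-of-max span also carries a few ramp samples at transit speed
    shelf <- range(which(d > max(d) - 0.001))
    bs <- vertical_speed(d[shelf[1]:shelf[2]], srs$dt)
    expect_true(all(abs(bs) < 0.02))
    expect_gte(shelf[1], seg$bottom[1])    # shelf contained in the bottom span
    expect_lte(shelf[2], seg$bottom[2])
    res <- classify_benthic(d, seg, srs$dt, p)
    expect_true(res$is_benthic)
  }
})

test_that("config validation rejects bad inputs", {
  expect_error(trip_config(n_days = 0), "n_days")
  expect_error(trip_config(noise_sd = -1), "noise_sd")
  expect_error(trip_config(type_mix = c(transit = 0.6, active_bottom = 0.6,
                                        benthic = 0, drift = 0)), "sum")
  expect_error(trip_config(track_speed = 5), "track_speed")
})

test_that("written trips round-trip through the CSV readers", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_sim_trip(sim, dir)
  back <- read_tdr(file.path(dir, "tdr.csv"))
  expect_equal(back$depth, round(sim$series$depth, 6), tolerance = 1e-6)
  expect_identical(as.numeric(back$time), as.numeric(sim$series$time))
  tr <- read_track(file.path(dir, "track.csv"))
  expect_equal(tr$lat, sim$track$lat, tolerance = 1e-6)
})
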