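test_that("intensity index matches hand-computed values", {
  expect_equal(intensity_index(5, 100, 20, 600), 25 + 25 * (100 / 600))
  expect_equal(intensity_index(8, 240, 30, 600), 89.6)
  expect_equal(intensity_index(0, 50, 10, 100), 0)
  expect_equal(intensity_index(3, 40, 0, 100), 0)   # flat bottom cannot be active
})

test_that("active-bottom cut is strict at the threshold", {
  # W=5, V=R=600, T=100 gives I = 5 * (1 + 6) = 35 exactly
  at <- list(W = 5, V = 600, R = 600, T = 100)
  expect_equal(intensity_index(at$W, at$V, at$R, at$T), 35)
  expect_false(classify_active_bottom(at))
  above <- list(W = 5, V = 600.01, R = 600, T = 100)
  expect_true(classify_active_bottom(above))
  expect_false(classify_active_bottom(list(W = 0, V = 100, R = 10, T = 100)))
})

test_that("vertical speed uses the buoyancy sign convention", {
  expect_equal(vertical_speed(rep(50, 5), 4), rep(0, 4))
  d <- seq(0, 12, by = 1.2)               # deepening 1.2 m per 4 s
  expect_equal(vertical_speed(d, 4), rep(-0.3, 10))
  # telescoping: sum(w) * dt = -(depth_end - depth_start)
  set.seed(1)
  x <- cumsum(rnorm(50))
  expect_equal(sum(vertical_speed(x, 4)) * 4, -(x[50] - x[1]))
})

test_that("speed density peak behaves like a density", {
  # near-point mass: peak at the value, height far above 1
  pk <- drift_kde(rep(-0.30, 60) + rnorm(60, 0, 1e-4), bw = 0.1)
  expect_lt(abs(pk$location + 0.30), 0.05)
  expect_gt(pk$height, 2)
  # uniform speeds on [-1, 1]: density about 0.5, no drift call
  set.seed(2)
  u <- runif(2000, -1, 1)
  pku <- drift_kde(u, bw = 0.1)
  expect_lt(abs(pku$height - 0.5), 0.15)
  expect_false(classify_drift(pku)$is_drift)
  # mass on the evaluation grid is 1 within 1e-3
  expect_lt(abs(pk$integral - 1), 1e-3)
  expect_lt(abs(pku$integral - 1), 1e-3)
  # too few samples: sentinel
  expect_true(is.na(drift_kde(rnorm(5))$location))
})

test_that("drift call is strict at density 1 and returns the rate", {
  expect_false(classify_drift(list(location = -0.2, height = 0.99))$is_drift)
  r <- classify_drift(list(location = -0.25, height = 1.2))
  expect_true(r$is_drift)
  expect_equal(r$drift_rate, -0.25)
})

test_that("synthetic drift dives are recovered with their rate", {
  p <- dive_params()
  hits <- 0
  for (rate in c(-0.35, -0.2, -0.12, 0.15, 0.3)) {
    s <- dive_spec("drift", 300, 900, drift_rate = rate, drift_fraction = 0.6,
                   leg_undulation = 0.5)
    d <- generate_dive_profile(s, 4)
    pk <- drift_kde(vertical_speed(d, 4), bw = p$kde_bandwidth)
    cl <- classify_drift(pk, p$drift_density_threshold)
    expect_true(cl$is_drift)
    if (abs(cl$drift_rate - rate) <= 0.05) hits <- hits + 1
  }
  expect_equal(hits, 5)
})

test_that("benthic detectors pass flat square dives and fail drifting ones", {
  p <- dive_params()
  b <- generate_dive_profile(dive_spec("benthic", 300, 800,
                                       leg_undulation = 0.5), 4)
  segb <- segment_phases(b)
  rb <- classify_benthic(b, segb, 4, p)
  expect_true(rb$kde_pass)
  expect_true(rb$corner_pass)
  expect_true(rb$is_benthic)

  dr <- generate_dive_profile(dive_spec("drift", 300, 900, drift_rate = -0.3,
                                        drift_fraction = 0.6), 4)
  segd <- segment_phases(dr)
  rd <- classify_benthic(dr, segd, 4, p)
  expect_false(rd$kde_pass)   # bottom-phase peak sits at -0.3, outside 0.08
  expect_false(rd$is_benthic)
})

test_that("rounded corners fail the square-corner test", {
  p <- dive_params()
  sharp <- generate_dive_profile(dive_spec("benthic", 300, 1100,
                                           descent_speed = 0.5,
                                           ascent_speed = 1.5), 4)
  expect_true(classify_benthic(sharp, segment_phases(sharp), 4, p)$corner_pass)
  # independent geometry: measure the corner mismatch of the smoothed profile
  corner_gap <- function(w) {
    d <- generate_dive_profile(dive_spec("benthic", 300, 2000,
                                         descent_speed = 0.5, ascent_speed = 1.5,
                                         corner_smoothing = w), 4)
    seg <- segment_phases(d)
    t <- (seq_along(d) - 1) * 4
    f <- function(i) stats::coef(stats::lm(d[i[1]:i[2]] ~ t[i[1]:i[2]]))
    c1 <- f(seg$descent); c2 <- f(seg$bottom)
    ts <- (c1[1] - c2[1]) / (c2[2] - c1[2])
    gap <- abs(stats::approx(t, d, ts)$y - (c1[1] + c1[2] * ts))
    res <- classify_benthic(d, seg, 4, p)
    expect_identical(res$corner_pass, unname(gap < p$corner_tolerance))
    gap
  }
  g60 <- corner_gap(60)
  g240 <- corner_gap(240)
  expect_gt(g240, g60)
  # a sufficiently blunt corner is rejected outright
  expect_gte(g240, p$corner_tolerance)
})

test_that("every dive gets exactly one label with benthic precedence", {
  sim <- small_sim()
  res <- run_pipeline(sim$series, sim$track)
  expect_equal(nrow(res$dives), nrow(detect_dives(res$series, params = dive_params())))
  expect_true(all(res$dives$dive_type %in% dive_types()))
  expect_equal(sum(table(res$dives$dive_type)), nrow(res$dives))
  # drift rate present iff labelled drift
  expect_true(all(is.finite(res$dives$drift_rate_ms) ==
                    (res$dives$dive_type == "drift")))
  # benthic dives that also clear the drift density threshold stay benthic
  dual <- res$dives$dive_type == "benthic" & res$dives$kde_peak_height > 1
  expect_gt(sum(dual), 0)
  expect_true(all(res$dives$dive_type[dual] == "benthic"))
})

test_that("labels are stable under small post-ZOC depth shifts and time translation", {
  sim <- small_sim()
  base <- classify_dives(sim$series, detect_dives(sim$series, params = dive_params()))
  for (c0 in c(-2, 2)) {
    s <- tdr_series("s", sim$series$time, pmax(sim$series$depth + c0, 0), dt = 4)
    shifted <- classify_dives(s, detect_dives(sim$series, params = dive_params()))
    expect_gte(mean(shifted$dive_type == base$dive_type), 0.98)
  }
  s2 <- tdr_series("s", sim$series$time + 86400 * 30, sim$series$depth, dt = 4)
  moved <- classify_dives(s2, detect_dives(s2, params = dive_params()))
  expect_identical(moved$dive_type, base$dive_type)
})
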