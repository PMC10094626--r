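# Novel tank readouts: analysis window, distance, latency, freezing.

tank64 <- function() tank_geometry(width_px = 300, height_px = 200, width_cm = 30)

test_that("the analysis window drops the skip span and truncates", {
  n <- 7 * 60 * 10 # 7 min at 10 fps
  tj <- xy_trajectory(seq_len(n), rep(50, n), fps = 10)
  w <- apply_analysis_window(tj, analysis_window(skip_s = 120, duration_s = 300))
  expect_equal(nrow(w$points), 3000L)
  expect_equal(w$start_frame, 1200L)
  # identity window
  w2 <- apply_analysis_window(tj, analysis_window(skip_s = 0, duration_s = Inf))
  expect_equal(w2$points, tj$points)
  # too-short trajectory
  short <- xy_trajectory(1:600, rep(50, 600), fps = 10) # 60 s
  expect_error(apply_analysis_window(short, analysis_window(skip_s = 120)),
               class = "noveltank_window_error")
})

test_that("distance sums Euclidean steps and converts by cm_per_px", {
  tank1 <- tank_geometry(width_px = 30, height_px = 20, width_cm = 30) # 1 cm/px
  tj <- xy_trajectory(c(0, 3), c(0, 4), fps = 10)
  expect_equal(total_distance(tj, tank1), 5)
  expect_equal(total_distance(xy_trajectory(5, 5), tank1), 0)
  # square loop of four 10-px sides at 0.1 cm/px
  tank01 <- tank_geometry(width_px = 300, height_px = 200, width_cm = 30)
  sq <- xy_trajectory(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0), fps = 10)
  expect_equal(total_distance(sq, tank01), 4)
})

test_that("distance is translation invariant and linear in calibration", {
  set.seed(13)
  x <- cumsum(rnorm(50)); y <- cumsum(rnorm(50))
  t1 <- xy_trajectory(x, y); t2 <- xy_trajectory(x + 17, y - 4)
  tank <- tank64()
  expect_equal(total_distance(t1, tank), total_distance(t2, tank))
  tank2 <- tank_geometry(width_px = 150, height_px = 200, width_cm = 30)
  expect_equal(total_distance(t1, tank2), 2 * total_distance(t1, tank))
})

test_that("latency is the first crossing above the midline", {
  tank <- tank64() # midline at row 100
  up_first <- xy_trajectory(1:10, rep(40, 10), fps = 10)
  expect_equal(latency_to_upper_half(up_first, tank)$latency_s, 0)
  y <- c(rep(150, 50), rep(60, 50))
  crossing <- xy_trajectory(seq_along(y), y, fps = 10)
  lat <- latency_to_upper_half(crossing, tank)
  expect_equal(lat$latency_s, 5)
  expect_false(lat$censored)
  never <- xy_trajectory(1:100, rep(150, 100), fps = 10)
  lat2 <- latency_to_upper_half(never, tank, analysis_window(duration_s = 300))
  expect_equal(lat2$latency_s, 300)
  expect_true(lat2$censored)
})

test_that("freezing counts only immobile runs at least one bout long", {
  fps <- 10
  cfg <- freezing_config(speed_threshold_px_per_frame = 0.5, min_bout_s = 1)
  # fully stationary 300-s window: all steps immobile, one quantum short
  n <- 300 * fps
  still <- xy_trajectory(rep(5, n), rep(5, n), fps = fps)
  expect_equal(freezing_duration(still, cfg), (n - 1) / fps)
  # continuously moving
  mover <- xy_trajectory(cumsum(rep(3, n)), rep(5, n), fps = fps)
  expect_equal(freezing_duration(mover, cfg), 0)
  # one 30-frame stationary run
  x <- c(cumsum(rep(3, 35)), rep(105, 30), cumsum(rep(3, 35)) + 105)
  run30 <- xy_trajectory(x, rep(5, length(x)), fps = fps)
  expect_equal(freezing_duration(run30, cfg), 3)
  # a 5-frame run is below the minimum bout
  x5 <- c(cumsum(rep(3, 35)), rep(105, 5), cumsum(rep(3, 35)) + 105)
  expect_equal(freezing_duration(xy_trajectory(x5, rep(5, length(x5)), fps = fps), cfg), 0)
})

test_that("freezing is monotone in threshold and minimum bout", {
  set.seed(29)
  for (rep_i in 1:10) {
    steps <- sample(c(0.1, 0.3, 1, 4), 200, replace = TRUE)
    x <- cumsum(steps)
    tj <- xy_trajectory(x, rep(0, length(x)), fps = 10)
    thr <- c(0.2, 0.5, 2, 5)
    fz_thr <- vapply(thr, function(s)
      freezing_duration(tj, freezing_config(speed_threshold_px_per_frame = s)),
      numeric(1))
    expect_true(all(diff(fz_thr) >= 0)) # lowering threshold never increases
    bouts <- c(0.5, 1, 2, 4)
    fz_bout <- vapply(bouts, function(b)
      freezing_duration(tj, freezing_config(min_bout_s = b)), numeric(1))
    expect_true(all(diff(fz_bout) <= 0)) # raising min bout never increases
  }
})

test_that("freezing plus moving time never exceeds the window", {
  set.seed(17)
  for (rep_i in 1:10) {
    n <- 400
    x <- cumsum(sample(c(0, 0, 3), n, replace = TRUE))
    tj <- xy_trajectory(x, rep(0, n), fps = 10)
    fz <- freezing_duration(tj)
    expect_lte(fz, n / 10)
  }
})

test_that("scripted metrics are recovered from ground-truth trajectories", {
  fps <- 10
  fractions <- rep(c(0, 0.2, 0.5), length.out = 50)
  for (i in seq_len(50)) {
    truth <- make_trajectory(e2e_script(seed = 1000 + i,
                                        freeze_fraction = fractions[i],
                                        duration_s = 60))
    tj <- truth_as_trajectory(truth)
    tank <- tank_geometry(width_px = 320, height_px = 240, width_cm = 30,
                          midline_row_px = 120)
    m <- summarize_behavior(tj, tank,
                            window = analysis_window(skip_s = 0, duration_s = 60))
    # distance: metric equals the path length of the script
    want_dist <- sum(sqrt(diff(truth$x_px)^2 + diff(truth$y_px)^2)) * tank$cm_per_px
    expect_equal(m$distance_cm, want_dist, tolerance = 1e-9)
    # freezing: within one frame quantum per bout edge of the scripted total
    expect_lt(abs(m$freezing_s - 60 * fractions[i]), 2 / fps + 0.2)
    # latency: matches the scripted first crossing
    cf <- attr(truth, "first_crossing_frame")
    if (is.na(cf)) {
      expect_true(m$latency_censored)
      expect_equal(m$latency_s, 60)
    } else {
      expect_lt(abs(m$latency_s - cf / fps), 2 / fps)
    }
  }
})

test_that("bottom dwellers are censored; scripted crossings match t*", {
  tank <- tank_geometry(width_px = 320, height_px = 240, midline_row_px = 120)
  win <- analysis_window(skip_s = 0, duration_s = 60)
  bd <- make_trajectory(behavior_script("bottom-dweller", seed = 4, fps = 10,
                                        duration_s = 60, midline_row_px = 120,
                                        bounds = e2e_bounds()))
  mb <- summarize_behavior(truth_as_trajectory(bd), tank, win)
  expect_true(mb$latency_censored)
  expect_equal(mb$latency_s, 60)

  cr <- make_trajectory(behavior_script("scripted-crossing", crossing_time_s = 20,
                                        seed = 4, fps = 10, duration_s = 60,
                                        midline_row_px = 120, bounds = e2e_bounds()))
  mc <- summarize_behavior(truth_as_trajectory(cr), tank, win)
  expect_false(mc$latency_censored)
  expect_equal(mc$latency_s, attr(cr, "first_crossing_frame") / 10)
  # the realized crossing happens at/after the scripted time, within the climb
  expect_gte(mc$latency_s, 20)
  expect_lt(mc$latency_s, 30)
})

test_that("summarize propagates window errors on empty windows", {
  tj <- xy_trajectory(1:50, rep(150, 50), fps = 10) # 5 s
  expect_error(summarize_behavior(tj, tank64(), analysis_window(skip_s = 120)),
               class = "noveltank_window_error")
})
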