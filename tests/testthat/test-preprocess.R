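test_that("kalman_smooth reproduces model-consistent tracks and denoises", {
  arena <- open_arena()
  # noiseless constant-velocity track passes through unchanged
  tr <- straight_tracklet("cv", 10, heading = 0.3, start = c(100, 100))
  sm <- kalman_smooth(tr, arena = arena)
  expect_equal(sm$x, tr$x, tolerance = 1e-4)
  expect_equal(sm$y, tr$y, tolerance = 1e-4)
  # static point + jitter: smoothed variance well below input variance
  set.seed(4)
  st <- tibble::tibble(tracklet_id = "st", t = seq(0, 99.9, by = 0.1),
                       x = 50 + rnorm(1000, 0, 0.1),
                       y = 50 + rnorm(1000, 0, 0.1))
  sms <- kalman_smooth(st, arena = arena)
  expect_lt(var(sms$x), var(st$x))
  expect_lt(var(sms$x), 0.1 * var(st$x))
  # single-sample tracklet returned unchanged
  one <- tibble::tibble(tracklet_id = "one", t = 0, x = 5, y = 5)
  expect_equal(kalman_smooth(one, arena = arena)$x, 5)
  # non-monotone timestamps rejected
  bad <- tr; bad$t[5] <- bad$t[4]
  expect_error(kalman_smooth(bad, arena = arena), "non-monotone")
})

test_that("split_tracklets splits at gaps and drops short segments", {
  tr <- tibble::tibble(t = seq(0, 9.9, by = 0.1), x = 1, y = 1)
  expect_equal(length(unique(split_tracklets(tr, 0.5)$tracklet_id)), 1)
  gap <- tr; gap$t[51:100] <- gap$t[51:100] + 2     # 2 s gap in middle
  expect_equal(length(unique(split_tracklets(gap, 0.5)$tracklet_id)), 2)
  expect_equal(nrow(split_tracklets(tr[0, ], 0.5)), 0)
  # min_samples filter
  tiny <- tibble::tibble(t = c(0:4 / 10, 10 + 0:59 / 10), x = 1, y = 1)
  out <- split_tracklets(tiny, 0.5, min_samples = 10)
  expect_equal(length(unique(out$tracklet_id)), 1)
  expect_equal(nrow(out), 60)
})

test_that("segment_activity labels walking / short-stop / resting", {
  set.seed(11)
  arena <- open_arena()
  # build a track: 60 s walk, 3 s stop, 60 s walk, 300 s rest, 60 s walk
  mk <- function(durs, moves) {
    t <- c(); x <- c(); cur_t <- 0; cur_x <- 0
    for (i in seq_along(durs)) {
      n <- durs[i] * 10
      seg_t <- cur_t + seq_len(n) / 10
      seg_x <- cur_x + if (moves[i]) cumsum(rep(0.02, n)) else rep(0, n)
      t <- c(t, seg_t); x <- c(x, seg_x)
      cur_t <- seg_t[n]; cur_x <- seg_x[n]
    }
    tibble::tibble(tracklet_id = "m", t = t,
                   x = 100 + x + rnorm(length(x), 0, 0.05),
                   y = 100 + rnorm(length(x), 0, 0.05))
  }
  tr <- mk(c(60, 3, 60, 300, 60), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  seg <- segment_activity(kalman_smooth(tr, arena = arena))
  # states partition all samples
  expect_true(all(seg$state %in% c("walking", "resting", "short_stop")))
  # the 3 s stationary run between walks is a short-stop event
  r <- rle(seg$state)
  expect_true("short_stop" %in% r$values)
  stops <- which(r$values == "short_stop")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (i in stops) {   # short-stops are bounded by walking on both sides
    expect_equal(r$values[i - 1], "walking")
    expect_equal(r$values[i + 1], "walking")
  }
  # the 300 s stationary run is resting
  expect_true("resting" %in% r$values)
  expect_gte(max(r$lengths[r$values == "resting"]), 2500)
  # constant-speed walking throughout -> all walking
  walk <- straight_tracklet("w", 12, heading = 0, start = c(100, 100))
  walk$x <- walk$x + rnorm(nrow(walk), 0, 0.05)
  walk$y <- walk$y + rnorm(nrow(walk), 0, 0.05)
  both <- dplyr::bind_rows(tr, walk)   # mixture needs both speed modes
  seg2 <- segment_activity(kalman_smooth(both, arena = arena))
  ww <- seg2[seg2$tracklet_id == "w", ]
  expect_gt(mean(ww$state == "walking"), 0.95)
  # tracklet too short to estimate speed -> unknown
  short <- tibble::tibble(tracklet_id = "u", t = c(0, 0.1),
                          x = c(1, 1), y = c(1, 1))
  expect_true(all(segment_activity(short)$state == "unknown"))
})

test_that("hourly_distance renormalizes by observed fraction", {
  # one fully observed hour of walking at 1 mm/s -> 3.6 m
  tr <- tibble::tibble(tracklet_id = "h", t = seq(0, 3600 - 0.1, by = 0.1),
                       x = 100 + seq(0, by = 0.01, length.out = 36000),
                       y = 100)
  tr$state <- "walking"
  hd <- hourly_distance(tr)
  expect_equal(hd$walked_distance_m[1], 3.6, tolerance = 0.01)
  expect_true(hd$included[1])
  # 50%-observed hour with 1 m recorded renormalizes to 2 m
  half <- tibble::tibble(
    tracklet_id = "g", t = seq(0, 1800 - 0.1, by = 0.1),
    x = 100 + seq(0, 100, length.out = 18000),  # 100 cm over 30 min
    y = 100, state = "walking")
  hd2 <- hourly_distance(half)
  expect_equal(hd2$observed_fraction[1], 0.5, tolerance = 0.01)
  expect_equal(hd2$walked_distance_m[1], 2, tolerance = 0.05)
  # halving the observed fraction doubles the estimate
  ov1 <- tibble::tibble(hour_index = 0, observed_fraction = 0.8)
  ov2 <- tibble::tibble(hour_index = 0, observed_fraction = 0.4)
  d1 <- hourly_distance(half, observed_fraction = ov1)$walked_distance_m
  d2 <- hourly_distance(half, observed_fraction = ov2)$walked_distance_m
  expect_equal(d2, 2 * d1)
  # 20%-observed hour excluded
  fifth <- tr[tr$t < 720, ]
  expect_false(hourly_distance(fifth)$included[1])
})

test_that("speed_distribution clips outliers at the 99th percentile", {
  tr <- tibble::tibble(speed = c(rep(0.2, 999), 50),
                       p_walk = rep(0.9, 1000))
  sd_ <- speed_distribution(tr)
  expect_lt(max(sd_$speed), 1)
  expect_equal(nrow(sd_), 999)   # the clip removes only the outlier
  # no walking samples -> empty
  none <- tibble::tibble(speed = 0.2, p_walk = 0.1)
  expect_equal(nrow(speed_distribution(none)), 0)
})

test_that("heading_series follows displacement and filters jitter", {
  xtr <- straight_tracklet("hx", 5, heading = 0, start = c(5, 5))
  expect_true(all(abs(heading_series(xtr)$heading) < 1e-9))
  ytr <- straight_tracklet("hy", 5, heading = pi / 2, start = c(5, 5))
  expect_true(all(abs(heading_series(ytr)$heading - pi / 2) < 1e-9))
  # stationary jitter below the 0.5 mm threshold yields nothing
  set.seed(2)
  jit <- tibble::tibble(tracklet_id = "j", t = 1:100 / 10,
                        x = 5 + rnorm(100, 0, 0.0001),
                        y = 5 + rnorm(100, 0, 0.0001))
  expect_equal(nrow(heading_series(jit)), 0)
})
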