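test_that("occupancy heatmap conserves observed time", {
  arena <- arena_geometry()
  # stationary tracklet: all mass in one cell
  st <- tibble::tibble(tracklet_id = "s", t = seq(0, 3600, by = 1),
                       x = 10.2, y = 10.2)
  hm <- occupancy_heatmap(st, arena)
  expect_equal(nrow(hm[hm$seconds > 0, ]), 1)
  expect_equal(sum(hm$seconds), 3600)
  # mixed tracklets: total mass equals total duration
  tr <- dplyr::bind_rows(
    straight_tracklet("a", 10, heading = 0, start = c(5, 5)),
    straight_tracklet("b", 8, heading = pi / 3, start = c(12, 20)))
  hm2 <- occupancy_heatmap(tr, arena)
  total <- tr |> dplyr::group_by(tracklet_id) |>
    dplyr::summarise(d = max(t) - min(t))
  expect_equal(sum(hm2$seconds), sum(total$d))
})

test_that("orientation distribution reflects motion direction", {
  xtr <- straight_tracklet("x", 10, heading = 0, start = c(5, 5))
  od <- orientation_distribution(xtr)
  expect_true(all(abs(od$heading) < 1e-9))
  # two opposite headings give a bimodal distribution
  both <- dplyr::bind_rows(
    straight_tracklet("up", 10, heading = pi / 2, start = c(5, 5)),
    straight_tracklet("down", 10, heading = -pi / 2, start = c(20, 20)))
  od2 <- orientation_distribution(both)
  expect_equal(sort(unique(round(od2$heading, 6))),
               c(-pi / 2, pi / 2), tolerance = 1e-6)
})

test_that("flow map takes per-cell circular means and masks sparse cells", {
  arena <- arena_geometry()
  tr <- straight_tracklet("f", 30, heading = 0, start = c(1, 10),
                          ds = 0.05)
  fm <- flow_map(tr, arena, min_count = 20)
  inc <- fm[fm$included, ]
  expect_gt(nrow(inc), 5)
  expect_true(all(abs(inc$direction) < 1e-6))
  expect_true(all(inc$resultant > 0.99))
  # direction equals the circular mean of contributing headings
  hs <- heading_series(tr)
  cell0 <- inc[1, ]
  contrib <- hs[floor((hs$x - arena$bbox[["xmin"]]) / 2) == cell0$ix &
                floor((hs$y - arena$bbox[["ymin"]]) / 2) == cell0$iy, ]
  cm <- circular_mean(contrib$heading)
  expect_equal(cell0$direction, cm$mean, tolerance = 1e-9)
  # two opposite passes cancel: resultant near zero
  fwd <- straight_tracklet("fw", 30, heading = 0, start = c(1, 10),
                           ds = 0.05)
  bwd <- fwd |> dplyr::arrange(dplyr::desc(t)) |>
    dplyr::mutate(t = max(fwd$t) + fwd$t, tracklet_id = "bw")
  fm2 <- flow_map(dplyr::bind_rows(fwd, bwd), arena, min_count = 20)
  expect_true(all(fm2$resultant[fm2$included] < 0.1))
})

test_that("directional Moran's I detects coherent fields", {
  # two coherent half-fields: left half east, right half west
  grid <- expand.grid(ix = 0:9, iy = 0:9)
  grid$direction <- ifelse(grid$ix < 5, 0, pi)
  grid$included <- TRUE
  flow <- tibble::as_tibble(grid)
  res <- morans_directional(flow, "rook", n_perm = 1000, seed = 3)
  expect_gt(res$I, 0)
  expect_lte(res$p_value, 0.01)
  # brute-force I for the constructed field (independent formula walk)
  U <- cbind(cos(flow$direction), sin(flow$direction))
  X <- sweep(U, 2, colMeans(U))
  num <- 0; W <- 0
  for (i in 1:100) for (j in 1:100) {
    if (i == j) next
    if (abs(flow$ix[i] - flow$ix[j]) + abs(flow$iy[i] - flow$iy[j]) == 1) {
      num <- num + sum(X[i, ] * X[j, ]); W <- W + 1
    }
  }
  I_brute <- (100 / W) * num / sum(X^2)
  expect_equal(res$I, I_brute, tolerance = 1e-12)
  # I is invariant to a global rotation of all directions
  rot <- flow; rot$direction <- wrap_angle(rot$direction + 1.1)
  res_rot <- morans_directional(rot, "rook", n_perm = 10, seed = 3)
  expect_equal(res_rot$I, res$I, tolerance = 1e-9)
})

test_that("Moran's I null behaves and degenerate inputs error", {
  set.seed(41)
  grid <- expand.grid(ix = 0:9, iy = 0:9)
  # independent uniform directions: I close to -1/(n-1) on average
  Is <- vapply(1:40, function(b) {
    g <- tibble::as_tibble(grid)
    g$direction <- stats::runif(100, -pi, pi)
    g$included <- TRUE
    morans_directional(g, "rook", n_perm = 2, seed = b)$I
  }, numeric(1))
  expect_equal(mean(Is), -1 / 99, tolerance = 0.02)
  # single unmasked cell -> error
  one <- tibble::tibble(ix = 0, iy = 0, direction = 0, included = TRUE)
  expect_error(morans_directional(one), "at least 10")
  # identical directions -> undefined
  g <- tibble::as_tibble(grid); g$direction <- 1; g$included <- TRUE
  expect_error(morans_directional(g, n_perm = 10), "identical")
  # queen neighborhood has more pairs than rook
  g2 <- tibble::as_tibble(grid)
  set.seed(1); g2$direction <- stats::runif(100, -pi, pi)
  g2$included <- TRUE
  pr_rook <- nrow(queenwalk:::neighbor_pairs(g2$ix, g2$iy, "rook"))
  pr_queen <- nrow(queenwalk:::neighbor_pairs(g2$ix, g2$iy, "queen"))
  expect_gt(pr_queen, pr_rook)
})

test_that("daily stop uniformity renormalizes and tests against uniform", {
  set.seed(42)
  # synthetic tracklets: homogeneous Poisson stops, 30 min each
  mk_tr <- function(id, hour, n_stops) {
    n <- 18000                      # 30 min at 10 Hz
    st <- rep("walking", n)
    if (n_stops > 0) {
      pos <- sort(sample.int(n - 200, n_stops))
      for (p in pos) st[p:(p + 30)] <- "short_stop"
    }
    tibble::tibble(tracklet_id = id, t = hour * 3600 + seq_len(n) / 10,
                   x = 1, y = 1, state = st)
  }
  trs <- dplyr::bind_rows(lapply(0:23, function(h) {
    dplyr::bind_rows(lapply(1:2, function(k) {
      mk_tr(sprintf("h%02d_%d", h, k), h, stats::rpois(1, 10))
    }))
  }))
  su <- daily_stop_uniformity(trs)
  expect_equal(nrow(su$hourly), 24)
  expect_gt(su$p_value, 0.05)
  expect_equal(su$df, 23)
  # renormalization: 10 stops in 30 min -> rate 20 per hour
  one <- mk_tr("r", 0, 10)
  su1 <- daily_stop_uniformity(one)
  expect_equal(su1$hourly$mean_rate[1], 20, tolerance = 0.01)
  # tracklets shorter than 5 min are excluded
  short <- mk_tr("s", 1, 5)[1:2400, ]
  expect_equal(daily_stop_uniformity(short)$n_tracklets, 0)
})

test_that("training_sample takes day one plus one distinct hour per day", {
  set.seed(43)
  # 4-day dataset, one 10-min tracklet every hour
  trs <- dplyr::bind_rows(lapply(0:95, function(k) {
    t0 <- k * 3600 + 600
    tibble::tibble(tracklet_id = sprintf("d%03d", k),
                   t = t0 + seq(0, 600, by = 1), x = 1, y = 1)
  }))
  sel <- training_sample(trs)
  spans <- sel |> dplyr::group_by(tracklet_id) |>
    dplyr::summarise(t0 = min(t))
  day <- floor(spans$t0 / 86400) + 1
  expect_equal(sum(day == 1), 24)           # all of day 1
  # days 2..4 contribute the tracklets overlapping hours 0, 1, 2
  for (k in 2:4) {
    hrs <- unique(floor((spans$t0[day == k] %% 86400) / 3600))
    expect_equal(hrs, (k - 2) %% 24)
  }
  # sub-day dataset returned whole with a warning
  short <- trs[trs$t < 43200, ]
  expect_warning(out <- training_sample(short), "shorter")
  expect_equal(nrow(out), nrow(short))
})

test_that("interstop distances are per-tracklet path distances", {
  # two stops 7 cm apart along a straight path
  tr <- straight_tracklet("i1", 20, heading = 0, start = c(5, 5))
  n <- nrow(tr)
  tr$state <- "walking"
  stop1 <- which.min(abs(tr$x - 10)); stop2 <- which.min(abs(tr$x - 17))
  tr$state[stop1] <- "short_stop"; tr$state[stop2] <- "short_stop"
  d <- interstop_distances(tr)
  expect_equal(nrow(d), 1)
  expect_equal(d$distance, 7, tolerance = 0.11)
  # stops in different tracklets yield no distance
  a <- tr; a$state <- "walking"; a$state[stop1] <- "short_stop"
  b <- a; b$tracklet_id <- "i2"
  expect_error(interstop_distances(dplyr::bind_rows(a, b)), "fewer than 2")
})
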