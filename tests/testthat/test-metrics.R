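test_that("ballistic diffusivity is exactly quadratic and MFP linear", {
  tr <- ballistic_ensemble(n = 35, length = 25, seed = 31)
  dc <- diffusivity_curve(tr)
  fit <- attr(dc, "fit")
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$b, 2, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  d <- tidy(dc)
  expect_equal(d$mean[d$abscissa == 10], 100, tolerance = 1e-9)
  mf <- mfp_curve(tr)
  mfit <- attr(mf, "fit")
  expect_equal(mfit$a, 1, tolerance = 1e-3)
  expect_equal(mfit$b, 1, tolerance = 1e-3)
})

test_that("diffusive walks show exponent 1 at scales beyond the mean step", {
  set.seed(32)
  tr <- dplyr::bind_rows(lapply(1:600, function(i)
    exp_walk_tracklet(sprintf("w%04d", i), target = 25, mean_step = 1)))
  dc <- diffusivity_curve(tr)
  d <- tidy(dc)
  keep <- d$abscissa >= 5 & d$abscissa <= 25
  fit <- fit_power(d$abscissa[keep], d$mean[keep])
  expect_equal(fit$b, 1, tolerance = 0.1)
  # single-point tracklets are excluded by the 5 cm filter
  one <- tibble::tibble(tracklet_id = "p", t = 1, x = 5, y = 5)
  expect_warning(dc0 <- diffusivity_curve(one), "qualifying")
  expect_true(all(is.na(tidy(dc0)$mean)))
})

test_that("MFP censors walks that never reach the threshold", {
  # 35 oscillating tracklets within 1 cm + 35 straight ones
  osc <- dplyr::bind_rows(lapply(1:35, function(i) {
    s <- seq(0, 30, by = 0.05)
    tibble::tibble(tracklet_id = sprintf("o%02d", i), t = seq_along(s),
                   x = 500 + 0.5 * sin(s * 4), y = 500)
  }))
  straight <- ballistic_ensemble(n = 35, length = 30, seed = 33)
  mf <- mfp_curve(dplyr::bind_rows(osc, straight))
  d <- tidy(mf)
  # above 1 cm displacement only the straight walkers contribute,
  # and for them first passage equals the displacement
  far <- d[d$abscissa > 1.5 & is.finite(d$mean), ]
  expect_equal(far$n_obs, rep(35, nrow(far)))
  expect_equal(far$mean, far$abscissa, tolerance = 1e-6)
})

test_that("disc coverage matches the stadium closed form within 1%", {
  big <- open_arena(100)
  area <- disc_coverage_area(c(-25, 25), c(0, 0), big)
  stadium <- 2 * 2.5 * 50 + pi * 2.5^2
  expect_lt(abs(area - stadium) / stadium, 0.01)
  # single point: one disc
  pt <- disc_coverage_area(c(0, 0), c(0, 0), big)
  expect_lt(abs(pt - pi * 2.5^2) / (pi * 2.5^2), 0.01)
  # retracing a segment twice covers the same area as tracing it once
  once <- disc_coverage_area(c(0, 10), c(0, 0), big)
  twice <- disc_coverage_area(c(0, 10, 0), c(0, 0, 0), big)
  expect_equal(twice, once)
})

test_that("coverage curve starts at the single-disc fraction and rises", {
  set.seed(34)
  arena <- arena_geometry()
  tr <- dplyr::bind_rows(lapply(1:35, function(i) {
    th <- stats::runif(1, 0, pi / 2)
    straight_tracklet(sprintf("c%02d", i), 15, heading = th,
                      start = c(8, 8))
  }))
  cc <- coverage_curve(tr, arena)
  d <- tidy(cc)
  disc_frac <- pi * 2.5^2 / (33 * 33)
  expect_equal(d$mean[d$abscissa == 0], disc_frac, tolerance = 0.05)
  expect_true(all(diff(d$mean[is.finite(d$mean)]) >= 0))  # non-decreasing
  fit <- attr(cc, "fit")
  expect_equal(fit$c, disc_frac, tolerance = 0.3)
})

test_that("self-crossing counts match the brute-force oracle", {
  set.seed(35)
  for (rep_i in 1:6) {
    # random 50-vertex polyline on a ~10 cm scale
    x <- cumsum(c(20, stats::rnorm(49, 0, 1.2)))
    y <- cumsum(c(20, stats::rnorm(49, 0, 1.2)))
    fast <- filter_crossings(polyline_crossings(x, y))
    slow <- brute_crossings(x, y)
    expect_equal(length(fast), length(slow))
    expect_equal(fast, slow, tolerance = 1e-9)
  }
  # straight line: no crossings
  expect_equal(nrow(polyline_crossings(c(0, 5, 10), c(0, 0, 0))), 0)
  # a loop with a transversal exit counts exactly one crossing
  th <- seq(0, 1.75 * pi, length.out = 200)
  lx <- c(4 + 3 * cos(th - pi / 2 * 1.5), 10)
  ly <- c(4 + 3 * sin(th - pi / 2 * 1.5), 8)
  cr <- filter_crossings(polyline_crossings(lx, ly))
  expect_equal(length(cr), length(brute_crossings(lx, ly)))
  # jitter loop of ~1 cm circumference is filtered out
  th2 <- seq(0, 2.4 * pi, length.out = 100)
  jx <- 5 + 0.159 * cos(th2); jy <- 5 + 0.159 * sin(th2)
  expect_equal(length(filter_crossings(polyline_crossings(jx, jy))), 0)
})

test_that("theoretical bounds hold and have their stated values", {
  expect_equal(theoretical_bounds("selfcross_max", 50), 20)
  expect_equal(theoretical_bounds("diffusivity_max", 5), 25)
  expect_equal(theoretical_bounds("mfp_min", 10), 10)
  expect_error(theoretical_bounds("nope", 1))
  arena <- arena_geometry()
  s <- seq(0, 25, by = 2.5)
  cb <- theoretical_bounds("coverage_max", s, arena)
  expect_true(all(diff(cb) >= 0))
  expect_true(all(cb <= 1))
  # bound dominates what straight tracklets achieve
  set.seed(36)
  tr <- dplyr::bind_rows(lapply(1:35, function(i)
    straight_tracklet(sprintf("s%02d", i), 25,
                      heading = stats::runif(1, 0, pi / 2),
                      start = c(4, 4))))
  cc <- tidy(coverage_curve(tr, arena, grid_step = 2.5))
  ok <- is.finite(cc$mean)
  bound <- theoretical_bounds("coverage_max", cc$abscissa[ok], arena)
  # the bound is grid-simulated (0.2 cm cells vs the curve's 0.1 cm),
  # so dominance is asserted up to rasterization noise
  expect_true(all(cc$mean[ok] <= bound * 1.02 + 1e-4))
})

test_that("curves respect their theoretical envelopes on random walks", {
  set.seed(37)
  tr <- dplyr::bind_rows(lapply(1:40, function(i)
    exp_walk_tracklet(sprintf("e%02d", i), target = 30, mean_step = 1)))
  d <- tidy(diffusivity_curve(tr))
  ok <- is.finite(d$mean)
  expect_true(all(d$mean[ok] <= d$abscissa[ok]^2 + 1e-9))
  m <- tidy(mfp_curve(tr))
  ok <- is.finite(m$mean)
  expect_true(all(m$mean[ok] >= m$abscissa[ok] - 1e-9))
  expect_true(all(diff(m$mean[ok]) >= -1e-9))        # MFP non-decreasing
  sc <- tidy(selfcross_curve(tr))
  ok <- is.finite(sc$mean)
  expect_true(all(sc$mean[ok] <= sc$abscissa[ok] / 2.5 + 1e-9))
  expect_true(all(diff(sc$mean[ok]) >= -1e-9))
})

test_that("fractal dimension spans line to near-plane and tracks turning", {
  # straight 30 cm line
  fd <- fractal_dimension(seq(0, 30, by = 0.1), rep(5, 301))
  expect_equal(fd$dimension, 1, tolerance = 0.02)
  # boustrophedon filling a 10 cm square at 2 mm pitch
  lanes <- seq(0.1, 9.9, by = 0.2)
  bx <- c(); by_ <- c()
  for (k in seq_along(lanes)) {
    xx <- if (k %% 2 == 1) c(0, 10) else c(10, 0)
    bx <- c(bx, xx); by_ <- c(by_, lanes[k], lanes[k])
  }
  fd2 <- fractal_dimension(bx + 5, by_ + 5)
  expect_gte(fd2$dimension, 1.8)
  # more turning (smaller kappa) raises the dimension monotonically
  set.seed(38)
  dims <- vapply(c(8, 1.5, 0.2), function(kap) {
    tf <- structure(list(family = "exponential", l_min = 0.2,
                         params = c(lambda = 1), logL = 0, AIC = 0, k = 1,
                         ks_distance = 0, n_tail = 1, n_dropped = 0,
                         converged = TRUE, akaike_weight = NA),
                    class = "tail_fit")
    vm <- structure(list(rho = 0, kappa = kap, R = 0, logL = 0, n = 100,
                         capped = FALSE), class = "vonmises_fit")
    mean(vapply(1:4, function(j) {
      w <- simulate_walk(walk_model(vm, tf), 60, seed = 1000 * kap + j)
      fractal_dimension(w$x, w$y)$dimension
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(dims) > 0))
  # fewer than 4 scales rejected
  expect_error(fractal_dimension(0:30, rep(1, 31), box_sizes = c(1, 2)),
               "4 box scales")
})
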