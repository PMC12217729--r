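# fixture builders shared across the suite; everything is generated in
# code so the repository ships no binary data

# straight-line tracklet of given length/heading, sampled every ds cm
straight_tracklet <- function(id = "s1", length = 20, heading = 0,
                              start = c(5, 5), ds = 0.1, speed = 0.2) {
  s <- seq(0, length, by = ds)
  tibble::tibble(tracklet_id = id, hive = 0L, comb = "lower",
                 side = "front", t = s / speed,
                 x = start[1] + s * cos(heading),
                 y = start[2] + s * sin(heading))
}

# ensemble of straight tracklets with random headings, kept inside a
# huge arena so confinement never interferes
ballistic_ensemble <- function(n = 40, length = 25, seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    straight_tracklet(sprintf("b%03d", i), length,
                      heading = stats::runif(1, -pi, pi),
                      start = c(500, 500))
  }))
}

# unconfined uncorrelated walk with exponential steps (mean_step cm)
exp_walk_tracklet <- function(id, target = 25, mean_step = 1,
                              start = c(500, 500)) {
  ls <- c(); tot <- 0
  while (tot < target) {
    l <- stats::rexp(1, 1 / mean_step)
    ls <- c(ls, l); tot <- tot + l
  }
  th <- stats::runif(length(ls), -pi, pi)
  x <- cumsum(c(start[1], ls * cos(th)))
  y <- cumsum(c(start[2], ls * sin(th)))
  tibble::tibble(tracklet_id = id, t = seq_along(x), x = x, y = y)
}

# a big open arena for tests that must not feel the walls
open_arena <- function(half = 1000) {
  arena_geometry(tibble::tibble(comb = "lower", xmin = -half,
                                ymin = -half, xmax = half, ymax = half))
}

# brute-force independent oracle: all-pairs O(n^2) segment intersection
# count with the same loop/inter-crossing filters, written as plain loops
brute_crossings <- function(x, y, min_loop = 2.5, min_between = 2.5) {
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  n <- length(x) - 1
  hits <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1) next
      rx <- x[i + 1] - x[i]; ry <- y[i + 1] - y[i]
      sx <- x[j + 1] - x[j]; sy <- y[j + 1] - y[j]
      den <- rx * sy - ry * sx
      if (abs(den) <= 1e-12) next
      qx <- x[j] - x[i]; qy <- y[j] - y[i]
      tt <- (qx * sy - qy * sx) / den
      uu <- (qx * ry - qy * rx) / den
      if (tt >= 0 && tt < 1 && uu >= 0 && uu < 1) {
        hits[[length(hits) + 1]] <-
          c(s[i] + tt * sqrt(rx^2 + ry^2), s[j] + uu * sqrt(sx^2 + sy^2))
      }
    }
  }
  if (!length(hits)) return(numeric(0))
  m <- do.call(rbind, hits)
  m <- m[m[, 2] - m[, 1] >= min_loop, , drop = FALSE]
  if (!nrow(m)) return(numeric(0))
  sl <- sort(m[, 2])
  counted <- numeric(0); last <- -Inf
  for (v in sl) {
    if (v - last >= min_between) { counted <- c(counted, v); last <- v }
  }
  counted
}

# independent grid-search likelihood maximizer for a 1-parameter tail
grid_mle_tail <- function(l, family, l_min, grid) {
  ll <- vapply(grid, function(p) {
    par <- switch(family, exponential = c(lambda = p),
                  squared_exponential = c(sigma = p),
                  pareto = c(mu = p))
    sum(dtail(l, family, par, l_min, log = TRUE))
  }, numeric(1))
  grid[which.max(ll)]
}

# independent grid-search von Mises kappa maximizer (rho fixed at 0)
grid_mle_kappa <- function(theta, grid) {
  ll <- vapply(grid, function(k) {
    sum(k * cos(theta)) - length(theta) *
      (log(besselI(k, 0, expon.scaled = TRUE)) + k + log(2 * pi))
  }, numeric(1))
  grid[which.max(ll)]
}
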