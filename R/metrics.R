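#' @name ensemble_metrics
#' @title Ensemble spatial-dynamics metrics
#' @description
#' Five properties of the walking process, each expressed against walked
#' distance (the queen's speed varies, so walked distance replaces time
#' throughout): diffusivity (squared displacement from the tracklet
#' start), mean first passage, areal coverage of the perceptive disc,
#' self-crossing counts, and the box-counting fractal dimension. Curves
#' are per-tracklet functions resampled onto a common abscissa grid by
#' linear interpolation, averaged across tracklets with interdecile
#' bands, and fitted with simple power models on `[0, 25]` cm.
NULL

# split a tracklet tibble into per-tracklet list of list(x, y), keeping
# only tracklets with walked length >= min_length (default the 5 cm filter)
tracklet_paths <- function(tracklets, min_length = 5) {
  paths <- split(tracklets[c("x", "y")], tracklets$tracklet_id)
  keep <- vapply(paths, function(p) {
    nrow(p) >= 2 && walked_length(p$x, p$y)[nrow(p)] >= min_length
  }, logical(1))
  paths[keep]
}

new_metric_curve <- function(df, kind, fit = NULL) {
  structure(df, kind = kind, fit = fit,
            class = c("metric_curve", class(df)))
}

#' Power-model fits for metric curves
#'
#' `fit_power()` fits `f(x) = a x^b` by least squares on log-log axes;
#' `fit_power_c()` fits `f(x) = a x^b + c` by nonlinear least squares.
#' R-squared is reported on the original scale.
#'
#' @param x abscissa values (> 0 for `fit_power`).
#' @param y curve values.
#' @return list `a`, `b` (and `c`), `r2`, `fit_range`.
#' @export
fit_power <- function(x, y) {
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) return(list(a = NA_real_, b = NA_real_, r2 = NA_real_,
                                 fit_range = range(x, na.rm = TRUE)))
  co <- stats::coef(stats::lm(log(y) ~ log(x)))
  a <- exp(co[[1]]); b <- co[[2]]
  pred <- a * x^b
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(a = a, b = b, r2 = r2, fit_range = range(x))
}

#' @rdname fit_power
#' @export
fit_power_c <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                                 r2 = NA_real_, fit_range = range(x)))
  c0 <- if (any(x == 0)) mean(y[x == 0]) else min(y)
  pos <- x > 0 & y > c0
  st <- if (sum(pos) >= 3) {
    co <- stats::coef(stats::lm(log(y[pos] - c0 + 1e-12) ~ log(x[pos])))
    list(a = exp(co[[1]]), b = co[[2]], c = c0)
  } else list(a = 1, b = 1, c = c0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^b + c, start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred <- st$a * x^st$b + st$c
    return(list(a = st$a, b = st$b, c = st$c,
                r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
                fit_range = range(x)))
  }
  co <- stats::coef(fit)
  pred <- co[["a"]] * x^co[["b"]] + co[["c"]]
  list(a = co[["a"]], b = co[["b"]], c = co[["c"]],
       r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
       fit_range = range(x))
}

# assemble mean/decile curve from list of per-tracklet (abscissa, value)
# step functions evaluated on a common grid
curve_from_samples <- function(values_by_tracklet, grid, min_obs = 30) {
  m <- do.call(cbind, values_by_tracklet)
  n_obs <- rowSums(is.finite(m))
  mean_v <- ifelse(n_obs >= min_obs, rowMeans(m, na.rm = TRUE), NA_real_)
  q10 <- q90 <- rep(NA_real_, length(grid))
  okrows <- which(n_obs >= min_obs)
  if (length(okrows)) {
    qs <- apply(m[okrows, , drop = FALSE], 1, stats::quantile,
                probs = c(0.1, 0.9), na.rm = TRUE)
    q10[okrows] <- qs[1, ]; q90[okrows] <- qs[2, ]
  }
  tibble::tibble(abscissa = grid, mean = mean_v, q10 = q10, q90 = q90,
                 n_obs = n_obs)
}

#' Diffusivity curve (mean squared displacement vs walked distance)
#'
#' For each tracklet the squared displacement from its start is traced
#' against cumulative walked distance; curves are interpolated to a
#' uniform grid and averaged across tracklets. A power model `a s^b` is
#' fitted to the mean on `[0, 25]` cm; `b = 2` is the ballistic
#' (straight-line) theoretical maximum and `b = 1` normal diffusion.
#'
#' @param tracklets tracklet tibble (positions in cm).
#' @param max_s largest walked distance (cm) on the grid. Default 25.
#' @param grid_step abscissa resolution (cm). Default 0.5.
#' @param min_obs minimal tracklets per abscissa to report a value.
#'   Default 30.
#' @param min_length tracklet walked-length filter (cm). Default 5.
#' @return a `metric_curve` tibble (`abscissa`, `mean`, `q10`, `q90`,
#'   `n_obs`) with the power fit in `attr(, "fit")`.
#' @export
diffusivity_curve <- function(tracklets, max_s = 25, grid_step = 0.5,
                              min_obs = 30, min_length = 5) {
  paths <- tracklet_paths(tracklets, min_length)
  grid <- seq(0, max_s, by = grid_step)
  if (length(paths) < min_obs) {
    warning("fewer than ", min_obs, " qualifying tracklets; empty curve")
    return(new_metric_curve(
      curve_from_samples(list(rep(NA_real_, length(grid))), grid, min_obs),
      "diffusivity"))
  }
  vals <- lapply(paths, function(p) {
    # 1 mm resampling keeps the convex d^2(s) interpolation from
    # overshooting the ballistic bound s^2 between sparse vertices
    rp <- resample_path(p$x, p$y, ds = 0.1)
    d2 <- (rp$x - rp$x[1])^2 + (rp$y - rp$y[1])^2
    stats::approx(rp$s, d2, xout = grid, rule = 1)$y
  })
  cur <- curve_from_samples(vals, grid, min_obs)
  fit <- fit_power(cur$abscissa[cur$abscissa <= 25],
                   cur$mean[cur$abscissa <= 25])
  new_metric_curve(cur, "diffusivity", fit)
}

#' Mean-first-passage curve
#'
#' For each displacement threshold `D` on the grid, the walked distance
#' at which a tracklet's displacement from its start first exceeds `D`,
#' averaged over the tracklets that ever reach `D` (others contribute
#' nothing at that `D`). The ballistic theoretical minimum is
#' `MFP(D) = D`. Power model `a D^b` fitted on `[0, 25]` cm.
#'
#' @inheritParams diffusivity_curve
#' @param max_D largest displacement threshold (cm). Default 25.
#' @return a `metric_curve`.
#' @export
mfp_curve <- function(tracklets, max_D = 25, grid_step = 0.5,
                      min_obs = 30, min_length = 5) {
  paths <- tracklet_paths(tracklets, min_length)
  grid <- seq(0, max_D, by = grid_step)
  if (length(paths) < min_obs) {
    warning("fewer than ", min_obs, " qualifying tracklets; empty curve")
    return(new_metric_curve(
      curve_from_samples(list(rep(NA_real_, length(grid))), grid, min_obs),
      "mfp"))
  }
  vals <- lapply(paths, function(p) {
    rp <- resample_path(p$x, p$y, ds = 0.1)
    d <- sqrt((rp$x - rp$x[1])^2 + (rp$y - rp$y[1])^2)
    env <- cummax(d)                     # nondecreasing reach envelope
    idx <- findInterval(grid, env, left.open = TRUE) + 1
    out <- rep(NA_real_, length(grid))
    reach <- idx <= length(env)
    ir <- idx[reach]
    sv <- rp$s[ir]
    # interpolate the crossing within the segment that first exceeds D
    interp <- reach & idx > 1
    ii <- idx[interp]
    den <- env[ii] - env[ii - 1]
    frac <- ifelse(den > 0, (grid[interp] - env[ii - 1]) / den, 1)
    out[reach] <- sv
    out[interp] <- rp$s[ii - 1] + frac * (rp$s[ii] - rp$s[ii - 1])
    out
  })
  cur <- curve_from_samples(vals, grid, min_obs)
  fit <- fit_power(cur$abscissa[cur$abscissa <= 25],
                   cur$mean[cur$abscissa <= 25])
  new_metric_curve(cur, "mfp", fit)
}

# --- coverage machinery -------------------------------------------------

# precompute integer cell offsets of a disc of radius r on a grid of
# cell size `cell` (offsets of cell centers within r of a point)
disc_offsets <- function(radius, cell) {
  k <- ceiling(radius / cell) + 1
  g <- expand.grid(dx = -k:k, dy = -k:k)
  keep <- (g$dx * cell)^2 + (g$dy * cell)^2 <= radius^2
  g[keep, ]
}

# accessible-cell mask for an arena on its coverage grid; returns list
# with nx, ny, mask (logical vector, column-major ix-major), n_accessible
coverage_grid <- function(arena, cell) {
  nx <- ceiling((arena$bbox["xmax"] - arena$bbox["xmin"]) / cell)
  ny <- ceiling((arena$bbox["ymax"] - arena$bbox["ymin"]) / cell)
  cx <- arena$bbox["xmin"] + (seq_len(nx) - 0.5) * cell
  cy <- arena$bbox["ymin"] + (seq_len(ny) - 0.5) * cell
  mask <- outer(cx, cy, function(X, Y) arena_contains(arena, X, Y))
  list(nx = as.integer(nx), ny = as.integer(ny), mask = as.vector(mask),
       n_accessible = sum(mask), cell = cell)
}

# incremental covered-cell counts along a path: returns covered count at
# each requested walked distance in `checkpoints`
incremental_coverage <- function(x, y, arena, grid, offs, checkpoints,
                                 mark_spacing = 0.25) {
  rp <- resample_path(x, y, ds = mark_spacing)
  covered <- logical(grid$nx * grid$ny)
  counts <- numeric(length(checkpoints))
  count <- 0
  ci <- 1
  ix0 <- floor((rp$x - arena$bbox[["xmin"]]) / grid$cell)
  iy0 <- floor((rp$y - arena$bbox[["ymin"]]) / grid$cell)
  for (i in seq_len(nrow(rp))) {
    while (ci <= length(checkpoints) && rp$s[i] > checkpoints[ci]) {
      counts[ci] <- count; ci <- ci + 1
    }
    ix <- ix0[i] + offs$dx
    iy <- iy0[i] + offs$dy
    ok <- ix >= 0 & ix < grid$nx & iy >= 0 & iy < grid$ny
    id <- ix[ok] * grid$ny + iy[ok] + 1
    id <- id[grid$mask[id] & !covered[id]]
    if (length(id)) { covered[id] <- TRUE; count <- count + length(id) }
  }
  while (ci <= length(checkpoints)) {
    if (checkpoints[ci] <= rp$s[nrow(rp)] + mark_spacing) {
      counts[ci] <- count
    } else counts[ci] <- NA_real_
    ci <- ci + 1
  }
  counts
}

#' Area covered by the perceptive disc along a path
#'
#' Grid estimate (1 mm cells by default) of the area swept by a disc of
#' `radius` centered on every point of the path, intersected with the
#' accessible region.
#'
#' @param x,y path vertices (cm).
#' @param arena an [arena_geometry()].
#' @param radius perceptive radius (cm). Default the arena's.
#' @param cell grid cell (cm). Default the arena's coverage cell.
#' @return covered area in cm^2.
#' @export
disc_coverage_area <- function(x, y, arena, radius = NULL, cell = NULL) {
  radius <- radius %||% arena$perceptive_radius
  cell <- cell %||% arena$coverage_cell
  grid <- coverage_grid(arena, cell)
  offs <- disc_offsets(radius, cell)
  s_total <- walked_length(x, y)[length(x)]
  cnt <- incremental_coverage(x, y, arena, grid, offs,
                              checkpoints = s_total)
  cnt[1] * cell^2
}

#' Areal-coverage curve
#'
#' Fraction of the accessible area (1 mm grid) covered by the queen's
#' perceptive disc (2.5 cm radius) as a function of cumulative walked
#' distance, averaged across tracklets. Power model `a s^b + c` fitted on
#' `[0, 25]` cm; the intercept `c` is the single-disc fraction.
#'
#' @inheritParams diffusivity_curve
#' @param arena an [arena_geometry()].
#' @return a `metric_curve` (values are fractions in `[0, 1]`).
#' @export
coverage_curve <- function(tracklets, arena = arena_geometry(),
                           max_s = 25, grid_step = 0.5, min_obs = 30,
                           min_length = 5) {
  paths <- tracklet_paths(tracklets, min_length)
  grid_s <- seq(0, max_s, by = grid_step)
  if (length(paths) < min_obs) {
    warning("fewer than ", min_obs, " qualifying tracklets; empty curve")
    return(new_metric_curve(
      curve_from_samples(list(rep(NA_real_, length(grid_s))), grid_s,
                         min_obs), "coverage"))
  }
  cg <- coverage_grid(arena, arena$coverage_cell)
  offs <- disc_offsets(arena$perceptive_radius, arena$coverage_cell)
  vals <- lapply(paths, function(p) {
    incremental_coverage(p$x, p$y, arena, cg, offs, grid_s) /
      cg$n_accessible
  })
  cur <- curve_from_samples(vals, grid_s, min_obs)
  fit <- fit_power_c(cur$abscissa[cur$abscissa <= 25],
                     cur$mean[cur$abscissa <= 25])
  new_metric_curve(cur, "coverage", fit)
}

# --- self-crossing machinery --------------------------------------------

#' Transversal self-intersections of a polyline
#'
#' Returns every transversal intersection of non-adjacent segments with
#' the walked distances of the two passes through the crossing point. A
#' half-open `[0, 1)` endpoint convention counts a crossing exactly at a
#' shared vertex once; collinear overlap segments count zero.
#'
#' @param x,y polyline vertices (cm).
#' @param s optional precomputed walked-length vector.
#' @return tibble `s_early`, `s_late` (cm), one row per intersection.
#' @export
polyline_crossings <- function(x, y, s = NULL) {
  n <- length(x) - 1
  if (n < 3) return(tibble::tibble(s_early = numeric(0),
                                   s_late = numeric(0)))
  if (is.null(s)) s <- walked_length(x, y)
  ij <- which(outer(seq_len(n), seq_len(n),
                    function(i, j) j > i + 1), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1]; y2 <- y[i + 1]
  x3 <- x[j]; y3 <- y[j]; x4 <- x[j + 1]; y4 <- y[j + 1]
  rx <- x2 - x1; ry <- y2 - y1
  sx <- x4 - x3; sy <- y4 - y3
  denom <- rx * sy - ry * sx
  qx <- x3 - x1; qy <- y3 - y1
  tt <- (qx * sy - qy * sx) / denom
  uu <- (qx * ry - qy * rx) / denom
  hit <- is.finite(tt) & is.finite(uu) &
    tt >= 0 & tt < 1 & uu >= 0 & uu < 1 & abs(denom) > 1e-12
  if (!any(hit)) return(tibble::tibble(s_early = numeric(0),
                                       s_late = numeric(0)))
  li <- sqrt(rx^2 + ry^2)[hit]; lj <- sqrt(sx^2 + sy^2)[hit]
  tibble::tibble(s_early = s[i[hit]] + tt[hit] * li,
                 s_late = s[j[hit]] + uu[hit] * lj)
}

#' Filter crossings by loop length and inter-crossing spacing
#'
#' Applies the jitter filters in path order: a crossing counts only when
#' the walked distance around its loop is at least `min_loop` and the
#' walked distance since the last counted crossing is at least
#' `min_between`.
#'
#' @param cross tibble from [polyline_crossings()].
#' @param min_loop,min_between filters (cm). Default 2.5.
#' @return sorted walked distances (`s_late`) of counted crossings.
#' @export
filter_crossings <- function(cross, min_loop = 2.5, min_between = 2.5) {
  cross <- cross[cross$s_late - cross$s_early >= min_loop, , drop = FALSE]
  if (!nrow(cross)) return(numeric(0))
  sl <- sort(cross$s_late)
  counted <- numeric(0)
  last <- -Inf
  for (v in sl) {
    if (v - last >= min_between) { counted <- c(counted, v); last <- v }
  }
  counted
}

#' Self-crossing curve
#'
#' Counts transversal intersections of each tracklet's path with itself
#' in path order; a crossing counts only when the walked distance around
#' the loop is at least `min_loop` and the walked distance since the last
#' counted crossing is at least `min_between` (both default 2.5 cm, the
#' perceptive radius, filtering jitter loops). Cumulative counts vs
#' walked distance, power model `a s^b + c` on `[0, 25]` cm.
#'
#' @inheritParams diffusivity_curve
#' @param min_loop,min_between filters (cm). Default 2.5.
#' @param resample_ds resampling step before intersection (cm).
#'   Default 0.1.
#' @return a `metric_curve`.
#' @export
selfcross_curve <- function(tracklets, min_loop = 2.5, min_between = 2.5,
                            max_s = 25, grid_step = 0.5, min_obs = 30,
                            min_length = 5, resample_ds = 0.1) {
  paths <- tracklet_paths(tracklets, min_length)
  grid <- seq(0, max_s, by = grid_step)
  if (length(paths) < min_obs) {
    warning("fewer than ", min_obs, " qualifying tracklets; empty curve")
    return(new_metric_curve(
      curve_from_samples(list(rep(NA_real_, length(grid))), grid, min_obs),
      "selfcross"))
  }
  vals <- lapply(paths, function(p) {
    rp <- resample_path(p$x, p$y, ds = resample_ds)
    cr <- polyline_crossings(rp$x, rp$y, rp$s)
    counted <- filter_crossings(cr, min_loop, min_between)
    total <- rp$s[nrow(rp)]
    out <- findInterval(grid, counted)
    out[grid > total] <- NA_real_
    as.numeric(out)
  })
  cur <- curve_from_samples(vals, grid, min_obs)
  fit <- fit_power_c(cur$abscissa[cur$abscissa <= 25],
                     cur$mean[cur$abscissa <= 25])
  new_metric_curve(cur, "selfcross", fit)
}

#' Theoretical bounds of the spatial-dynamics metrics
#'
#' * `diffusivity_max(s) = s^2` (ballistic straight line),
#' * `mfp_min(D) = D` (ballistic),
#' * `selfcross_max(s) = s / 2.5` (a crossing every perceptive radius),
#' * `coverage_max(s)`: fastest coverage attained by simulated
#'   boustrophedon (snake) sweeps of the perceptive disc over the comb
#'   from different start corners/orientations, plus the straight
#'   diagonal, taken pointwise maximal (a simulated, not closed-form,
#'   bound).
#'
#' @param kind one of `"diffusivity_max"`, `"mfp_min"`,
#'   `"selfcross_max"`, `"coverage_max"`.
#' @param s_or_D walked distance or displacement threshold (cm).
#' @param arena an [arena_geometry()], used for the coverage bound.
#' @param min_between the self-crossing spacing (cm). Default 2.5.
#' @return numeric vector of bound values (coverage as a fraction).
#' @export
theoretical_bounds <- function(kind, s_or_D, arena = arena_geometry(),
                               min_between = 2.5) {
  kind <- match.arg(kind, c("diffusivity_max", "mfp_min",
                            "selfcross_max", "coverage_max"))
  s <- s_or_D
  stopifnot(all(s >= 0))
  switch(kind,
    diffusivity_max = s^2,
    mfp_min = s,
    selfcross_max = s / min_between,
    coverage_max = coverage_bound(s, arena))
}

# fastest-coverage bound by simulated meandric sweeps
coverage_bound <- function(s, arena) {
  cg <- coverage_grid(arena, max(arena$coverage_cell, 0.2))
  offs <- disc_offsets(arena$perceptive_radius, cg$cell)
  smax <- max(s)
  paths <- meander_paths(arena, smax)
  best <- rep(0, length(s))
  for (p in paths) {
    cnt <- incremental_coverage(p$x, p$y, arena, cg, offs, s)
    cnt[is.na(cnt)] <- max(cnt, 0, na.rm = TRUE)
    best <- pmax(best, cnt / cg$n_accessible)
  }
  best
}

# boustrophedon sweep polylines (+ the straight diagonal) of total
# length >= smax over the arena bounding box
meander_paths <- function(arena, smax) {
  r <- arena$perceptive_radius
  bb <- arena$bbox
  pitch <- 2 * r
  mk <- function(horizontal, from_low) {
    if (horizontal) {
      lanes <- seq(bb["ymin"] + r, bb["ymax"] - r, by = pitch)
      if (!from_low) lanes <- rev(lanes)
      xs <- c(bb["xmin"] + r, bb["xmax"] - r)
      x <- c(); y <- c()
      for (k in seq_along(lanes)) {
        xx <- if (k %% 2 == 1) xs else rev(xs)
        x <- c(x, xx); y <- c(y, lanes[k], lanes[k])
      }
      list(x = x, y = y)
    } else {
      lanes <- seq(bb["xmin"] + r, bb["xmax"] - r, by = pitch)
      if (!from_low) lanes <- rev(lanes)
      ys <- c(bb["ymin"] + r, bb["ymax"] - r)
      x <- c(); y <- c()
      for (k in seq_along(lanes)) {
        yy <- if (k %% 2 == 1) ys else rev(ys)
        y <- c(y, yy); x <- c(x, lanes[k], lanes[k])
      }
      list(x = x, y = y)
    }
  }
  # reference straight line inset by r so its disc is never clipped by
  # the boundary (a clipped disc would understate the feasible rate)
  diagonal <- list(x = c(bb["xmin"] + r, bb["xmax"] - r),
                   y = c(bb["ymin"] + r, bb["ymax"] - r))
  list(mk(TRUE, TRUE), mk(TRUE, FALSE), mk(FALSE, TRUE), mk(FALSE, FALSE),
       diagonal)
}

#' Box-counting fractal dimension of a path
#'
#' The polyline is rasterized at 0.5 mm arc-length spacing; for each box
#' size `eps` the number `N(eps)` of occupied boxes (grid anchored at the
#' arena origin) is counted, and `D` is minus the slope of the
#' least-squares line of `log N(eps)` on `log eps`, with `sd` the
#' regression standard error of the slope.
#'
#' @param x,y path vertices (cm), walked length at least `min_length`.
#' @param box_sizes box sizes (cm); default 12 geometric scales from 0.2
#'   to 10. At least 4 required.
#' @param origin grid anchor. Default `c(0, 0)` (arena origin).
#' @param min_length minimal walked length (cm). Default 5.
#' @return list of class `fractal_estimate`: `dimension`, `sd`,
#'   `box_sizes`, `box_counts`.
#' @export
fractal_dimension <- function(x, y, box_sizes = NULL, origin = c(0, 0),
                              min_length = 5) {
  if (is.null(box_sizes)) {
    box_sizes <- exp(seq(log(0.2), log(10), length.out = 12))
  }
  if (length(box_sizes) < 4) stop("need at least 4 box scales")
  total <- walked_length(x, y)[length(x)]
  if (total < min_length) {
    stop("path walked length ", signif(total, 3), " cm below the ",
         min_length, " cm filter")
  }
  rp <- resample_path(x, y, ds = 0.05)
  # minimum count over sub-box grid translations removes the anchoring
  # bias of plain box counting (a straight line then scales as 1/eps)
  shifts <- seq(0, 0.75, by = 0.25)
  counts <- vapply(box_sizes, function(eps) {
    min(vapply(shifts, function(ox) {
      min(vapply(shifts, function(oy) {
        ix <- floor((rp$x - origin[1] - ox * eps) / eps)
        iy <- floor((rp$y - origin[2] - oy * eps) / eps)
        length(unique(ix * 1e6 + iy))
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  # scales where only a handful of boxes are occupied carry a ceiling
  # bias of relative size up to 1/N (a segment needs ceil(L/eps) boxes);
  # regress on scales with N >= 20 so that bias stays below 5%
  use <- counts >= 20
  if (sum(use) < 4) use <- rank(-counts, ties.method = "first") <= 4
  fitlm <- stats::lm(log(counts[use]) ~ log(box_sizes[use]))
  sl <- summary(fitlm)$coefficients
  structure(list(dimension = -sl[2, 1], sd = sl[2, 2],
                 box_sizes = box_sizes, box_counts = counts,
                 used = use),
            class = "fractal_estimate")
}

#' @export
print.fractal_estimate <- function(x, ...) {
  cat(sprintf("<fractal_estimate> D = %.3f +/- %.3f (%d box scales)\n",
              x$dimension, x$sd, length(x$box_sizes)))
  invisible(x)
}

#' @export
print.metric_curve <- function(x, ...) {
  fit <- attr(x, "fit")
  cat("<metric_curve> ", attr(x, "kind"), ", ", nrow(x), " grid points\n",
      sep = "")
  if (!is.null(fit) && is.finite(fit$b %||% NA)) {
    cat(sprintf("  fit: a = %.4g, b = %.4g%s, R^2 = %.4f\n", fit$a, fit$b,
                if (!is.null(fit$c)) sprintf(", c = %.4g", fit$c) else "",
                fit$r2))
  }
  NextMethod()
}
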