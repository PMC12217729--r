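#' Confined step-and-turn walk model
#'
#' Bundles a turning-angle model (a [fit_vonmises()] fit or `"uniform"`),
#' a step-length tail ([fit_tail()]), an optional sub-`l_min` body
#' ([fit_body()]) and the arena. Step lengths are drawn from the
#' body/tail mixture truncated to the feasible interval `[0, L]` given
#' the walker's position and new heading, so a simulated walker can never
#' exit the comb area.
#'
#' @param turn a `vonmises_fit` or the string `"uniform"`.
#' @param tail a `tail_fit`.
#' @param body a `body_fit` or `NULL` (tail only).
#' @param arena an [arena_geometry()].
#' @return list of class `walk_model`.
#' @export
walk_model <- function(turn, tail, body = NULL,
                       arena = arena_geometry()) {
  stopifnot(inherits(tail, "tail_fit"),
            is.null(body) || inherits(body, "body_fit"))
  uniform_turn <- identical(turn, "uniform")
  if (!uniform_turn) stopifnot(inherits(turn, "vonmises_fit"))
  structure(list(turn = turn, uniform_turn = uniform_turn, tail = tail,
                 body = body, arena = arena),
            class = "walk_model")
}

# mixture CDF at q of body (mass m on [0, l_min]) + tail (mass 1 - m on
# [l_min, ...)); model is a walk_model
step_mixture_cdf <- function(model, q) {
  t <- model$tail
  m <- if (is.null(model$body)) 0 else model$body$mass
  pt <- ptail(q, t$family, t$params, t$l_min)
  if (m > 0 && is.finite(model$body$scale)) {
    m * pbody(q, model$body$scale, t$l_min) + (1 - m) * pt
  } else {
    pt
  }
}

# inverse-CDF draw of one step length truncated to [0, L]
sample_step_length <- function(model, L) {
  FL <- step_mixture_cdf(model, L)
  if (FL <= 0) return(NA_real_)          # nothing feasible along heading
  u <- stats::runif(1, 0, FL)
  t <- model$tail
  m <- if (is.null(model$body)) 0 else model$body$mass
  if (m > 0 && is.finite(model$body$scale) &&
      u < m * pbody(L, model$body$scale, t$l_min)) {
    qbody(u / m, model$body$scale, t$l_min)
  } else {
    v <- (u - (if (m > 0 && is.finite(model$body$scale))
      m * pbody(L, model$body$scale, t$l_min) else 0)) / (1 - m)
    qtail(pmin(v, 1 - 1e-12), t$family, t$params, t$l_min)
  }
}

#' Simulate one confined step-and-turn walk
#'
#' Starts uniformly in the accessible region with a uniform initial
#' heading; each step turns by a draw from the turning model and draws a
#' length from the body/tail mixture truncated by inverse-CDF sampling to
#' the feasible length `L` along the new heading (confinement
#' truncation). If no length is feasible along a heading (on the
#' boundary, heading outward), the heading is resampled uniformly — the
#' escape rule. The walk stops once its cumulative length reaches
#' `target_length`.
#'
#' @param model a [walk_model()].
#' @param target_length walked length to generate (cm).
#' @param seed RNG seed; `NULL` continues the current RNG stream.
#' @param start optional `c(x, y)` start (otherwise uniform).
#' @return tibble `step`, `x`, `y`, `s` (cumulative walked distance) of
#'   the step vertices, starting at step 0.
#' @export
simulate_walk <- function(model, target_length, seed = NULL,
                          start = NULL) {
  stopifnot(target_length > 0)
  if (!is.null(seed)) set.seed(seed)
  arena <- model$arena
  if (is.null(start)) {
    repeat {
      sx <- stats::runif(1, arena$bbox[["xmin"]], arena$bbox[["xmax"]])
      sy <- stats::runif(1, arena$bbox[["ymin"]], arena$bbox[["ymax"]])
      if (arena_contains(arena, sx, sy)) break
    }
    start <- c(sx, sy)
  }
  x <- numeric(256); y <- numeric(256)
  x[1] <- start[1]; y[1] <- start[2]
  heading <- stats::runif(1, -pi, pi)
  s <- 0; k <- 1
  while (s < target_length) {
    proposal <- if (k == 1) heading else if (model$uniform_turn) {
      stats::runif(1, -pi, pi)
    } else {
      heading + rvonmises(1, model$turn$rho, model$turn$kappa)
    }
    L <- feasible_length(arena, x[k], y[k], proposal)
    l <- if (L > 1e-9) sample_step_length(model, L) else NA_real_
    if (!is.finite(l) || l <= 0) {       # escape rule: resample heading
      proposal <- stats::runif(1, -pi, pi)
      L <- feasible_length(arena, x[k], y[k], proposal)
      l <- if (L > 1e-9) sample_step_length(model, L) else NA_real_
      if (!is.finite(l) || l <= 0) next
    }
    l <- min(l, L)
    heading <- proposal
    k <- k + 1
    if (k > length(x)) { x <- c(x, numeric(length(x)))
                         y <- c(y, numeric(length(y))) }
    x[k] <- x[k - 1] + l * cos(heading)
    y[k] <- y[k - 1] + l * sin(heading)
    s <- s + l
  }
  tibble::tibble(step = 0:(k - 1), x = x[1:k], y = y[1:k],
                 s = walked_length(x[1:k], y[1:k]))
}

#' Simulate an ensemble matched to empirical tracklet lengths
#'
#' One simulated trajectory per qualifying empirical tracklet (walked
#' length at least `min_length`), each with the matching target length,
#' resampled to 1 mm arc length so simulated and empirical inputs go
#' through the metric computations identically.
#'
#' @param model a [walk_model()].
#' @param tracklets empirical tracklet tibble.
#' @param seed RNG seed.
#' @param min_length qualifying-length filter (cm). Default 5.
#' @param label model label attached as attribute.
#' @return tracklet-dialect tibble (`tracklet_id`, `t`, `x`, `y`; time is
#'   walked distance at unit speed) with attributes `label` and `seed`.
#' @export
simulate_matched_ensemble <- function(model, tracklets, seed = 1,
                                      min_length = 5, label = NULL) {
  paths <- tracklet_paths(tracklets, min_length)
  lens <- vapply(paths, function(p) walked_length(p$x, p$y)[nrow(p)],
                 numeric(1))
  set.seed(seed)
  sims <- lapply(seq_along(lens), function(i) {
    w <- simulate_walk(model, lens[i])
    rp <- resample_path(w$x, w$y, ds = 0.1)
    tibble::tibble(tracklet_id = sprintf("sim_%05d", i),
                   t = rp$s, x = rp$x, y = rp$y)
  })
  out <- dplyr::bind_rows(sims)
  attr(out, "label") <- label %||% model$tail$family
  attr(out, "seed") <- seed
  out
}

#' Compare a simulated ensemble to empirical metric curves
#'
#' Recomputes diffusivity, mean first passage, coverage and self-crossing
#' on the simulated ensemble with identical parameters and grids, and
#' reports, per metric, the signed area between the simulated and
#' empirical mean curves on `[0, 25]` cm and whether the simulated mean
#' lies inside the empirical interdecile band.
#'
#' @param sim simulated tracklet tibble (e.g. from
#'   [simulate_matched_ensemble()]).
#' @param empirical_curves named list with elements `diffusivity`, `mfp`,
#'   `coverage`, `selfcross` (any subset), each a `metric_curve`.
#' @param arena an [arena_geometry()] (for coverage).
#' @param min_obs curve clipping threshold, matching the empirical
#'   curves. Default 30.
#' @return tibble `metric`, `signed_area`, `frac_within_band`,
#'   `within_band`; simulated curves in the list-column `sim_curve`.
#' @export
compare_to_empirical <- function(sim, empirical_curves,
                                 arena = arena_geometry(), min_obs = 30) {
  mk <- function(kind) {
    switch(kind,
      diffusivity = diffusivity_curve(sim, min_obs = min_obs),
      mfp = mfp_curve(sim, min_obs = min_obs),
      coverage = coverage_curve(sim, arena, min_obs = min_obs),
      selfcross = selfcross_curve(sim, min_obs = min_obs))
  }
  rows <- lapply(names(empirical_curves), function(kind) {
    emp <- empirical_curves[[kind]]
    sc <- mk(kind)
    if (!isTRUE(all.equal(emp$abscissa, sc$abscissa))) {
      stop("mismatched abscissa grids for metric '", kind, "'")
    }
    ok <- is.finite(emp$mean) & is.finite(sc$mean) & emp$abscissa <= 25
    area <- if (sum(ok) >= 2) {
      diffs <- sc$mean[ok] - emp$mean[ok]
      sum(diff(emp$abscissa[ok]) * (head(diffs, -1) + tail(diffs, -1)) / 2)
    } else NA_real_
    inband <- sc$mean[ok] >= emp$q10[ok] & sc$mean[ok] <= emp$q90[ok]
    tibble::tibble(metric = kind, signed_area = area,
                   frac_within_band = mean(inband),
                   within_band = all(inband),
                   sim_curve = list(sc))
  })
  dplyr::bind_rows(rows)
}
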