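#' Maximum-likelihood von Mises fit of turning angles
#'
#' The mean direction is the circular mean; the concentration `kappa` is
#' obtained by numeric inversion of the mean-resultant-length relation
#' `A1(kappa) = I1(kappa) / I0(kappa) = R` (Best-Fisher-style starting
#' approximation refined by root finding).
#'
#' @param turns turning angles in radians, or a steps tibble with a
#'   `turn` column.
#' @param kappa_max cap on the fitted concentration for (near-)degenerate
#'   samples. Default 500.
#' @param gap half-width (radians) of an excluded window around zero
#'   turn. Geometric changepoint detectors cannot split near-straight
#'   paths, so the detected turn distribution has an unreliable gap
#'   around 0 rad (shallow corners go missing while noise splits inject
#'   spurious near-zero turns). With `gap > 0` the fit maximizes the von
#'   Mises likelihood conditional on `|turn| >= gap`, making the
#'   estimate independent of that region. Default 0 (plain MLE).
#' @return object of class `vonmises_fit` with `rho`, `kappa`, `R`,
#'   `logL`, `n`.
#' @export
fit_vonmises <- function(turns, kappa_max = 500, gap = 0) {
  if (is.data.frame(turns)) turns <- turns$turn
  turns <- turns[is.finite(turns)]
  if (gap > 0) turns <- turns[abs(turns) >= gap]
  n <- length(turns)
  if (n < 10) stop("need at least 10 turning angles, got ", n)
  cm <- circular_mean(turns)
  R <- cm$R
  if (gap == 0) {
    kappa <- solve_kappa(R, kappa_max)
    capped <- kappa >= kappa_max
    if (capped) warning("kappa capped at ", kappa_max,
                        " (near-degenerate angles)")
    logL <- n * kappa * R - n * log_bessel_i0(kappa) -
      n * base::log(2 * pi)
    return(structure(list(rho = cm$mean, kappa = kappa, R = R,
                          logL = logL, n = n, capped = capped, gap = 0),
                     class = "vonmises_fit"))
  }
  # conditional MLE on |turn| >= gap
  nll <- function(par) {
    rho <- wrap_angle(par[1]); kap <- exp(par[2])
    if (kap > kappa_max) return(1e10)
    pgap <- tryCatch(stats::integrate(dvonmises, -gap, gap, rho = rho,
                                      kappa = kap)$value,
                     error = function(e) NA_real_)
    if (!is.finite(pgap) || pgap >= 1 - 1e-10) return(1e10)
    -(sum(kap * cos(turns - rho)) - n * log_bessel_i0(kap) -
        n * base::log(2 * pi) - n * base::log(1 - pgap))
  }
  o <- stats::optim(c(cm$mean, base::log(max(solve_kappa(R, kappa_max),
                                             1e-3))),
                    nll, method = "Nelder-Mead",
                    control = list(maxit = 1000, reltol = 1e-10))
  kappa <- exp(o$par[2])
  structure(list(rho = wrap_angle(o$par[1]), kappa = kappa, R = R,
                 logL = -o$value, n = n, capped = kappa >= kappa_max,
                 gap = gap),
            class = "vonmises_fit")
}

log_bessel_i0 <- function(kappa) {
  base::log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

A1 <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

solve_kappa <- function(R, kappa_max = 500) {
  if (R <= 1e-8) return(0)
  # Best & Fisher starting approximation
  k0 <- if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
  if (!is.finite(k0) || k0 >= kappa_max || A1(kappa_max) <= R) {
    return(kappa_max)
  }
  stats::uniroot(function(k) A1(k) - R, lower = 0, upper = kappa_max,
                 f.lower = -R, tol = 1e-10)$root
}

#' von Mises density and sampler
#'
#' @param theta angles (radians).
#' @param n sample size.
#' @param rho mean direction (radians).
#' @param kappa concentration (>= 0); 0 gives the circular uniform.
#' @return density values / sampled angles in `(-pi, pi]`.
#' @export
dvonmises <- function(theta, rho = 0, kappa = 1) {
  exp(kappa * cos(theta - rho) - log_bessel_i0(kappa)) / (2 * pi)
}

#' @rdname dvonmises
#' @export
rvonmises <- function(n, rho = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  # Best-Fisher wrapped-Cauchy envelope rejection sampler
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rr <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r2 <- (1 + rr^2) / (2 * rr)
  out <- numeric(n)
  got <- 0
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r2 * z) / (r2 + z)
    cc <- kappa * (r2 - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (base::log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[keep] - 0.5) * acos(f[keep])
    take <- min(length(th), m)
    if (take > 0) out[(got + 1):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  wrap_angle(out + rho)
}

#' Confinement-aware MLE of a step-length tail family
#'
#' Fits one of the five tail families to step lengths `l >= l_min` by
#' numerical maximum likelihood. Each observation's likelihood is the
#' family density renormalized to the feasible interval
#' `[l_min, L_i]`, where `L_i` is the feasible length of that step to the
#' arena boundary; this implements the confinement truncation (the walker
#' cannot exit the comb area). With `L_i = Inf` (or no `feasible` column)
#' the fit reduces to the ordinary unconfined MLE.
#'
#' @param steps steps tibble (columns `length` and optionally `feasible`)
#'   or a numeric vector of step lengths.
#' @param family tail family name, see [tail_families].
#' @param l_min tail start (cm).
#' @param b_max upper bound of the truncated Pareto (cm); defaults to
#'   the default arena diagonal (the longest possible straight-line
#'   motion). By default the bound is held fixed at this physical scale
#'   (`fit_b = FALSE`): fitting it instead makes the truncated Pareto
#'   collapse onto the plain Pareto with `b` at the sample maximum,
#'   where AIC cannot separate the two.
#' @param fit_b estimate the truncated-Pareto upper bound as a free
#'   parameter instead of fixing it at `b_max`. Default FALSE.
#' @param n_tail_min minimal number of tail observations. Default 50.
#' @return object of class `tail_fit` with `family`, `l_min`, `params`,
#'   `logL`, `AIC`, `ks_distance`, `n_tail`, `n_dropped`, `converged`.
#' @export
fit_tail <- function(steps, family, l_min, b_max = NULL, fit_b = FALSE,
                     n_tail_min = 50) {
  family <- check_family(family)
  if (is.data.frame(steps)) {
    l <- steps$length
    L <- if ("feasible" %in% names(steps)) steps$feasible else
      rep(Inf, length(l))
  } else {
    l <- as.numeric(steps)
    L <- rep(Inf, length(l))
  }
  keep <- is.finite(l) & l >= l_min
  l <- l[keep]; L <- L[keep]
  drop <- L < l_min
  n_dropped <- sum(drop)
  l <- l[!drop]; L <- L[!drop]
  L <- pmax(L, l)  # feasibility can never be shorter than the step taken
  n <- length(l)
  if (n < n_tail_min) {
    stop("only ", n, " tail observations at l_min = ", signif(l_min, 4),
         "; need >= ", n_tail_min)
  }
  if (is.null(b_max)) b_max <- arena_geometry()$diagonal
  max_l <- max(l)
  if (family == "truncated_pareto" && !fit_b && max_l > b_max) {
    # data exceed the fixed upper bound: the family is infeasible here
    return(structure(list(family = family, l_min = l_min,
                          params = c(mu = NA_real_, b = b_max),
                          logL = -Inf, AIC = Inf, k = 1,
                          ks_distance = NA_real_, n_tail = n,
                          n_dropped = n_dropped, converged = FALSE,
                          akaike_weight = NA_real_),
                     class = "tail_fit"))
  }
  finite_L <- is.finite(L) & L < b_max * 100
  negll <- function(theta) {
    par <- tail_theta_to_params(theta, family, l_min, max_l, b_max)
    ld <- dtail(l, family, par, l_min, log = TRUE)
    if (any(!is.finite(ld))) return(1e10)
    val <- -sum(ld)
    if (any(finite_L)) {
      FL <- ptail(L[finite_L], family, par, l_min)
      if (any(FL <= 0)) return(1e10)
      val <- val + sum(base::log(FL))
    }
    if (!is.finite(val)) return(1e10)
    val
  }
  th0 <- tail_start_theta(family, l, l_min, b_max, fit_b)
  opt <- if (length(th0) == 1) {
    o <- stats::optim(th0, negll, method = "Brent",
                      lower = th0 - 15, upper = th0 + 15)
    o
  } else {
    stats::optim(th0, negll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
  }
  params <- tail_theta_to_params(opt$par, family, l_min, max_l, b_max)
  logL <- -opt$value
  k <- n_tail_params(family, fit_b)
  ks <- tail_ks_distance(l, family, params, l_min)
  structure(list(family = family, l_min = l_min, params = params,
                 logL = logL, AIC = 2 * k - 2 * logL, k = k,
                 ks_distance = ks, n_tail = n, n_dropped = n_dropped,
                 converged = opt$convergence == 0,
                 akaike_weight = NA_real_),
            class = "tail_fit")
}

# KS distance between the empirical tail CDF and the fitted model CDF
tail_ks_distance <- function(l, family, params, l_min) {
  l <- sort(l)
  n <- length(l)
  Fm <- ptail(l, family, params, l_min)
  Fe_hi <- seq_len(n) / n
  Fe_lo <- (seq_len(n) - 1) / n
  max(abs(Fe_hi - Fm), abs(Fe_lo - Fm))
}

#' Select the tail start l_min by minimal KS distance
#'
#' Fits the family over a grid of candidate `l_min` values (log-spaced
#' between low and high empirical quantiles of the step lengths) and
#' returns the fit whose Kolmogorov-Smirnov distance between the fitted
#' and empirical tail CDFs is smallest.
#'
#' @inheritParams fit_tail
#' @param n_candidates grid size. Default 50.
#' @param q_range quantile range of the candidate grid. Default
#'   `c(0.01, 0.90)`.
#' @return the selected `tail_fit`; the full scan is attached as
#'   attribute `"scan"` (tibble `l_min`, `ks_distance`, `n_tail`).
#' @export
scan_lmin <- function(steps, family, n_candidates = 50,
                      q_range = c(0.01, 0.90), b_max = NULL,
                      n_tail_min = 50) {
  l <- if (is.data.frame(steps)) steps$length else as.numeric(steps)
  l <- l[is.finite(l) & l > 0]
  qs <- stats::quantile(l, q_range, names = FALSE)
  if (qs[1] <= 0) qs[1] <- min(l[l > 0])
  cand <- unique(exp(seq(base::log(qs[1]), base::log(qs[2]),
                         length.out = n_candidates)))
  fits <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    fits[i] <- list(tryCatch(              # [[<- NULL would drop the slot
      fit_tail(steps, family, cand[i], b_max = b_max,
               n_tail_min = n_tail_min),
      error = function(e) NULL))
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("no candidate l_min leaves >= ", n_tail_min, " tail observations")
  }
  scan <- tibble::tibble(
    l_min = cand[ok],
    ks_distance = vapply(fits[ok], function(f) f$ks_distance, numeric(1)),
    n_tail = vapply(fits[ok], function(f) f$n_tail, numeric(1)))
  best <- fits[ok][[which.min(scan$ks_distance)]]
  attr(best, "scan") <- scan
  best
}

#' Akaike weights across tail fits on common support
#'
#' `weight_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`. The fits must be on the same data and
#' the same `l_min` (AIC across different supports is not comparable).
#'
#' @param fits list of `tail_fit` objects.
#' @return the list with `akaike_weight` filled in.
#' @export
akaike_weights <- function(fits) {
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "tail_fit")))
  lm <- vapply(fits, function(f) f$l_min, numeric(1))
  nn <- vapply(fits, function(f) f$n_tail, numeric(1))
  if (length(unique(round(lm, 10))) != 1 || length(unique(nn)) != 1) {
    stop("fits are on different data (l_min or n_tail differ); ",
         "refit on a common support first")
  }
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  d <- aic - min(aic)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  for (i in seq_along(fits)) fits[[i]]$akaike_weight <- w[i]
  fits
}

#' Select the best-supported tail family
#'
#' Families whose AIC lies within `parsimony_margin` of the minimum are
#' statistically indistinguishable (the conventional two-unit support
#' interval); among them the one with the fewest parameters is selected,
#' with remaining ties broken by Akaike weight. This protects the
#' selection against boundary-nested pairs (an exponentially truncated
#' Pareto with vanishing exponent is an exponential; with vanishing decay
#' it is a Pareto), where the richer family can win a small spurious
#' likelihood gain.
#'
#' @param fits list of `tail_fit` objects on common support (see
#'   [akaike_weights()]).
#' @param parsimony_margin AIC support margin. Default 2.
#' @return the selected `tail_fit`.
#' @export
select_best_family <- function(fits, parsimony_margin = 2) {
  fits <- akaike_weights(fits)
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  w <- vapply(fits, function(f) f$akaike_weight, numeric(1))
  cand <- which(aic <= min(aic) + parsimony_margin)
  cand <- cand[order(k[cand], -w[cand])]
  fits[[cand[1]]]
}

#' Fit and compare tail families by Akaike weight
#'
#' Runs [scan_lmin()] per family, refits every family on the common
#' support `[max selected l_min, Inf)` so the likelihoods are comparable,
#' and computes Akaike weights. Set `mode = "per_family"` to keep each
#' family at its own selected `l_min` (weights are then indicative only).
#'
#' @inheritParams fit_tail
#' @param families families to compare. Default all five.
#' @param mode `"common"` (default) or `"per_family"` support.
#' @param ... passed to [scan_lmin()].
#' @return tibble with one row per family (`family`, `l_min`, parameter
#'   columns, `logL`, `AIC`, `akaike_weight`, `ks_distance`, `n_tail`);
#'   fitted objects in the list-column `fit`.
#' @export
compare_families <- function(steps, families = tail_family_names,
                             mode = c("common", "per_family"), ...) {
  mode <- match.arg(mode)
  sel <- lapply(families, function(f) scan_lmin(steps, f, ...))
  if (mode == "common") {
    l_common <- max(vapply(sel, function(f) f$l_min, numeric(1)))
    sel <- lapply(families, function(f) fit_tail(steps, f, l_common))
  }
  sel <- akaike_weights(sel)
  best <- select_best_family(sel)$family
  tibble::tibble(
    selected = vapply(sel, function(f) f$family, character(1)) == best,
    family = vapply(sel, function(f) f$family, character(1)),
    l_min = vapply(sel, function(f) f$l_min, numeric(1)),
    logL = vapply(sel, function(f) f$logL, numeric(1)),
    AIC = vapply(sel, function(f) f$AIC, numeric(1)),
    akaike_weight = vapply(sel, function(f) f$akaike_weight, numeric(1)),
    ks_distance = vapply(sel, function(f) f$ks_distance, numeric(1)),
    n_tail = vapply(sel, function(f) f$n_tail, numeric(1)),
    fit = sel
  ) |> dplyr::arrange(dplyr::desc(.data$akaike_weight))
}

#' Bootstrap uncertainty of tail parameters
#'
#' Resamples steps with replacement `B` times; each resample goes through
#' the full `scan_lmin` + fit, and per-parameter means and standard
#' deviations are reported.
#'
#' @inheritParams scan_lmin
#' @param B number of bootstrap resamples. Default 200.
#' @param seed RNG seed (required for reproducibility).
#' @return tibble `parameter`, `mean`, `sd`, with attributes `n_failed`
#'   and `flagged` (TRUE when more than 20% of resample fits failed).
#' @export
bootstrap_params <- function(steps, family, B = 200, seed = 1, ...) {
  set.seed(seed)
  if (!is.data.frame(steps)) steps <- tibble::tibble(length = steps)
  draws <- list()
  n_failed <- 0
  for (b in seq_len(B)) {
    res <- steps[sample.int(nrow(steps), replace = TRUE), ]
    f <- tryCatch(scan_lmin(res, family, ...), error = function(e) NULL)
    if (is.null(f) || !f$converged) { n_failed <- n_failed + 1; next }
    draws[[length(draws) + 1]] <- c(f$params, l_min = f$l_min)
  }
  if (!length(draws)) stop("all bootstrap resample fits failed")
  m <- do.call(rbind, draws)
  out <- tibble::tibble(parameter = colnames(m),
                        mean = colMeans(m),
                        sd = apply(m, 2, stats::sd))
  attr(out, "n_failed") <- n_failed
  attr(out, "flagged") <- n_failed > 0.2 * B
  out
}

#' Fit the sub-l_min body of the step distribution
#'
#' The body is a half-truncated normal on `[0, l_min]` with location
#' `l_min`; its probability mass equals the empirical CDF of the steps at
#' `l_min` and its scale is fitted by MLE to the sub-`l_min` steps.
#'
#' @inheritParams fit_tail
#' @return object of class `body_fit` with `mass`, `scale`, `l_min`,
#'   `n_body`. With no steps below `l_min`, `mass` is 0 and `scale` `NA`.
#' @export
fit_body <- function(steps, l_min) {
  l <- if (is.data.frame(steps)) steps$length else as.numeric(steps)
  l <- l[is.finite(l) & l > 0]
  body <- l[l < l_min]
  mass <- length(body) / length(l)
  if (!length(body)) {
    return(structure(list(mass = 0, scale = NA_real_, l_min = l_min,
                          n_body = 0), class = "body_fit"))
  }
  nll <- function(log_sigma) {
    sg <- exp(log_sigma)
    Z <- stats::pnorm(0, sd = 1) - stats::pnorm(-l_min / sg)  # mass on [0, l_min]
    sum((body - l_min)^2) / (2 * sg^2) + length(body) *
      (base::log(sg) + base::log(Z) + 0.5 * base::log(2 * pi))
  }
  o <- stats::optimize(nll, interval = base::log(c(1e-4 * l_min,
                                                   100 * l_min)))
  structure(list(mass = mass, scale = exp(o$minimum), l_min = l_min,
                 n_body = length(body)),
            class = "body_fit")
}

# body (half-truncated normal on [0, l_min], location l_min) CDF/quantile
pbody <- function(q, scale, l_min) {
  lo <- stats::pnorm(-l_min / scale)
  num <- stats::pnorm((pmin(q, l_min) - l_min) / scale) - lo
  pmax(0, num / (0.5 - lo))
}

qbody <- function(u, scale, l_min) {
  lo <- stats::pnorm(-l_min / scale)
  l_min + scale * stats::qnorm(lo + u * (0.5 - lo))
}

#' Training-sample selection for model fitting
#'
#' Takes the first observation day completely and, from each following
#' day `k`, the tracklets overlapping wall-clock hour `(k - 2) mod 24` of
#' that day, so the selected hours are pairwise distinct until day 25.
#'
#' @param tracklets tracklet tibble (`t` in seconds from dataset start,
#'   assumed to start at midnight unless `t0_hour` is given).
#' @param t0_hour wall-clock hour at `t = 0`. Default 0.
#' @return the selected subset of rows.
#' @export
training_sample <- function(tracklets, t0_hour = 0) {
  span <- range(tracklets$t)
  if (diff(span) < 86400) {
    warning("dataset shorter than one day; returning it whole")
    return(tracklets)
  }
  spans <- tracklets |>
    dplyr::group_by(.data$tracklet_id) |>
    dplyr::summarise(t_min = min(.data$t), t_max = max(.data$t))
  day <- floor(spans$t_min / 86400) + 1          # 1-based day of t_min
  keep <- day == 1
  for (k in sort(unique(day[day >= 2]))) {
    h <- (k - 2) %% 24
    w0 <- (k - 1) * 86400 + ((h - t0_hour) %% 24) * 3600
    keep <- keep | (spans$t_min < w0 + 3600 & spans$t_max >= w0)
  }
  dplyr::semi_join(tracklets,
                   spans[keep, "tracklet_id"], by = "tracklet_id")
}

#' Walked distances between consecutive short-stops
#'
#' Along each tracklet, the walked path distance between consecutive
#' short-stop events (stops in different tracklets yield no distance).
#' The resulting distances are typically fitted with
#' `scan_lmin(distances, "pareto")`.
#'
#' @param tracklets segmented tracklet tibble (needs `state`).
#' @return tibble `tracklet_id`, `distance` (cm).
#' @export
interstop_distances <- function(tracklets) {
  out <- tracklets |>
    dplyr::group_by(.data$tracklet_id) |>
    dplyr::group_modify(function(d, key) {
      s <- walked_length(d$x, d$y)
      r <- rle(d$state == "short_stop")
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      stops <- which(r$values)
      if (length(stops) < 2) return(tibble::tibble(distance = numeric(0)))
      # event position: path position at the middle of the stop run
      pos <- vapply(stops, function(i) {
        s[floor((starts[i] + ends[i]) / 2)]
      }, numeric(1))
      tibble::tibble(distance = diff(pos))
    }) |>
    dplyr::ungroup()
  if (nrow(out) == 0) {
    stop("fewer than 2 short-stops in every tracklet")
  }
  out
}

#' Daily uniformity of short-stop rates
#'
#' Uses tracklets longer than `min_duration`; per tracklet the number of
#' short-stops is renormalized to a full hour (stops per hour), rates are
#' averaged per wall-clock hour of day, and the 24 hourly means are
#' tested against their grand mean with a chi-square goodness-of-fit test
#' (df = number of observed hours - 1).
#'
#' @param tracklets segmented tracklet tibble (needs `state`).
#' @param t0_hour wall-clock hour at `t = 0`. Default 0.
#' @param min_duration minimal tracklet duration (seconds). Default 300.
#' @return object of class `stop_uniformity`: tibble of hourly mean rates
#'   plus `statistic`, `df`, `p_value`, `mean_rate`, `ci` (95% CI of the
#'   overall rate) and `missing_hours`.
#' @export
daily_stop_uniformity <- function(tracklets, t0_hour = 0,
                                  min_duration = 300) {
  per_tr <- tracklets |>
    dplyr::group_by(.data$tracklet_id) |>
    dplyr::summarise(
      duration = max(.data$t) - min(.data$t),
      n_stops = sum(rle(.data$state == "short_stop")$values),
      hour = (t0_hour + floor(((min(.data$t) + max(.data$t)) / 2) /
                                3600)) %% 24
    ) |>
    dplyr::filter(.data$duration > min_duration) |>
    dplyr::mutate(rate = .data$n_stops / (.data$duration / 3600))
  hourly <- per_tr |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(mean_rate = mean(.data$rate),
                     n_tracklets = dplyr::n())
  missing_hours <- setdiff(0:23, hourly$hour)
  obs <- hourly$mean_rate
  expd <- rep(mean(obs), length(obs))
  stat <- sum((obs - expd)^2 / expd)
  df <- length(obs) - 1
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  r <- per_tr$rate
  ci <- if (length(r) >= 2) {
    mean(r) + stats::qt(c(0.025, 0.975), df = length(r) - 1) *
      stats::sd(r) / sqrt(length(r))
  } else c(NA_real_, NA_real_)
  structure(list(hourly = hourly, statistic = stat, df = df, p_value = p,
                 mean_rate = mean(r), ci = ci,
                 missing_hours = missing_hours,
                 n_tracklets = nrow(per_tr)),
            class = "stop_uniformity")
}

#' @export
print.vonmises_fit <- function(x, ...) {
  cat(sprintf(
    "<vonmises_fit> rho = %.4f rad, kappa = %.4f (R = %.4f, n = %d)\n",
    x$rho, x$kappa, x$R, x$n))
  invisible(x)
}

#' @export
print.tail_fit <- function(x, ...) {
  cat("<tail_fit> ", x$family, " tail on [", signif(x$l_min, 4),
      ", Inf) cm\n  ", paste(names(x$params), "=",
                             signif(x$params, 4), collapse = ", "),
      "\n  logL = ", signif(x$logL, 6), ", AIC = ", signif(x$AIC, 6),
      ", KS = ", signif(x$ks_distance, 4), ", n = ", x$n_tail, "\n",
      sep = "")
  invisible(x)
}

#' @export
print.body_fit <- function(x, ...) {
  cat(sprintf(
    "<body_fit> mass %.3f below l_min = %.3g cm, scale = %.3g cm (n = %d)\n",
    x$mass, x$l_min, x$scale, x$n_body))
  invisible(x)
}

#' @export
print.stop_uniformity <- function(x, ...) {
  cat(sprintf(
    "<stop_uniformity> chi^2 = %.3f, df = %d, p = %.3g; mean rate %.2f/h (95%% CI %.2f-%.2f)\n",
    x$statistic, x$df, x$p_value, x$mean_rate, x$ci[1], x$ci[2]))
  invisible(x)
}
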