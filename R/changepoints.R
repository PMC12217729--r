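#' Changepoint detector parameters
#'
#' @param window covariance window as walked distance (cm); the window is
#'   centered on each path point, making the detector speed-invariant.
#'   Default 0.6, matching the scale of the queen's typical step (mean
#'   about 1 cm) so adjacent corners are resolved.
#' @param min_ratio threshold on the eigenvalue ratio
#'   `lambda_minor / lambda_major` below which local maxima are ignored.
#'   Default 0.0017: after pre-smoothing, the ratio's noise floor along
#'   straight runs of Kalman-smoothed 10 Hz data sits near 0.001, while
#'   the shallow corners a von Mises walker actually takes still clear
#'   this threshold.
#' @param nms_radius non-maximum-suppression radius (cm of walked
#'   distance). Default 0.25.
#' @param resample_ds arc-length resampling step (cm). Default 0.1 (1 mm).
#' @param presmooth arc-length box-smoothing span (cm) applied to the
#'   resampled path before the covariance ratio is computed. Default 0.3.
#'   Averaging over ~3 mm of arc shrinks the jitter-driven ratio floor by
#'   about an order of magnitude while corners at the window scale are
#'   untouched, which is what lets `min_ratio` sit low enough to catch
#'   the shallow (10-25 degree) corners a concentrated von Mises walker
#'   mostly takes.
#' @return list of class `changepoint_params`.
#' @export
changepoint_params <- function(window = 0.6, min_ratio = 0.0017,
                               nms_radius = 0.25, resample_ds = 0.1,
                               presmooth = 0.3) {
  stopifnot(window > 0, min_ratio >= 0, min_ratio < 1, nms_radius >= 0,
            resample_ds > 0, presmooth >= 0)
  structure(list(window = window, min_ratio = min_ratio,
                 nms_radius = nms_radius, resample_ds = resample_ds,
                 presmooth = presmooth),
            class = "changepoint_params")
}

# centered box smoothing of a vector; ends fall back to the raw values
box_smooth <- function(v, k) {
  if (k < 2 || length(v) < k + 2) return(v)
  f <- stats::filter(v, rep(1 / k, k), sides = 2)
  f[is.na(f)] <- v[is.na(f)]
  as.numeric(f)
}

#' Resample a path to uniform arc-length spacing
#'
#' Linear interpolation of the polyline at points `0, ds, 2 ds, ...`
#' along its walked (arc) length; the final vertex is always kept.
#'
#' @param x,y polyline vertices (cm).
#' @param ds spacing (cm). Default 0.1.
#' @return tibble `s`, `x`, `y`.
#' @export
resample_path <- function(x, y, ds = 0.1) {
  s <- walked_length(x, y)
  keep <- c(TRUE, diff(s) > 0)            # drop exactly stationary repeats
  s <- s[keep]; x <- x[keep]; y <- y[keep]
  total <- s[length(s)]
  if (length(s) < 2 || total < ds) {
    return(tibble::tibble(s = s[1], x = x[1], y = y[1]))
  }
  grid <- seq(0, total, by = ds)
  if (total - grid[length(grid)] > ds / 2) grid <- c(grid, total)
  else grid[length(grid)] <- total
  gx <- stats::approx(s, x, xout = grid)$y
  gy <- stats::approx(s, y, xout = grid)$y
  tibble::tibble(s = grid, x = gx, y = gy)
}

# eigenvalue ratio lambda_minor / lambda_major of windowed positional
# covariance along a uniformly resampled path; k = half window in samples
eigen_ratio_profile <- function(x, y, k) {
  n <- length(x)
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x^2); cyy <- cumsum(y^2); cxy <- cumsum(x * y)
  lo <- pmax(1, seq_len(n) - k)
  hi <- pmin(n, seq_len(n) + k)
  m <- hi - lo + 1
  S  <- function(cs) cs[hi] - c(0, cs)[lo]
  sx <- S(cx); sy <- S(cy)
  sxx <- S(cxx); syy <- S(cyy); sxy <- S(cxy)
  vxx <- sxx / m - (sx / m)^2
  vyy <- syy / m - (sy / m)^2
  vxy <- sxy / m - (sx / m) * (sy / m)
  tr <- vxx + vyy
  disc <- sqrt(pmax(0, (vxx - vyy)^2 + 4 * vxy^2))
  lmax <- (tr + disc) / 2
  lmin <- (tr - disc) / 2
  ifelse(lmax > 1e-12, pmax(0, lmin) / lmax, 0)
}

#' Detect changepoints by the eigenvalue-ratio corner criterion
#'
#' Each tracklet is resampled to uniform 1 mm arc-length spacing; at each
#' point the 2x2 covariance of the positions in the centered
#' walked-distance window is computed and the ratio
#' `r = lambda_minor / lambda_major` formed. Changepoints are local
#' maxima of `r` with `r >= min_ratio`, thinned by non-maximum
#' suppression (ties broken by earliest path position); the path
#' endpoints are always included. By default only walking-state samples
#' are used when a `state` column is present.
#'
#' @param tracklets tracklet tibble.
#' @param params a [changepoint_params()] object.
#' @param walking_only drop non-walking samples first. Default TRUE.
#' @return tibble `tracklet_id`, `cp` (index into the resampled path),
#'   `s` (walked distance, cm), `x`, `y`.
#' @export
detect_changepoints <- function(tracklets, params = changepoint_params(),
                                walking_only = TRUE) {
  if (walking_only && "state" %in% names(tracklets)) {
    tracklets <- dplyr::filter(tracklets, .data$state %in%
                                 c("walking", "short_stop"))
  }
  tracklets |>
    dplyr::group_by(.data$tracklet_id) |>
    dplyr::group_modify(function(d, key) {
      rp <- resample_path(d$x, d$y, params$resample_ds)
      n <- nrow(rp)
      if (n < 2) {
        return(tibble::tibble(cp = 1L, s = rp$s, x = rp$x, y = rp$y))
      }
      idx <- c(1L, n)
      if (rp$s[n] > params$window) {
        kp <- round((params$presmooth %||% 0) / params$resample_ds)
        sx <- box_smooth(rp$x, kp)
        sy <- box_smooth(rp$y, kp)
        k <- max(1L, round(params$window / 2 / params$resample_ds))
        r <- eigen_ratio_profile(sx, sy, k)
        interior <- which(
          r >= params$min_ratio &
            r >= c(-Inf, r[-n]) &         # non-strict: a constant-
            r >= c(r[-1], -Inf))          # curvature plateau is all
                                          # candidates; NMS thins it
        interior <- setdiff(interior, c(1L, n))
        if (length(interior)) {
          ord <- interior[order(-r[interior], rp$s[interior])]
          kept <- integer(0)
          for (i in ord) {
            if (!length(kept) ||
                all(abs(rp$s[kept] - rp$s[i]) >= params$nms_radius)) {
              kept <- c(kept, i)
            }
          }
          idx <- sort(unique(c(idx, kept)))
        }
      }
      tibble::tibble(cp = idx, s = rp$s[idx], x = rp$x[idx], y = rp$y[idx])
    }) |>
    dplyr::ungroup()
}

#' Steps and turning angles between changepoints
#'
#' Step length is the Euclidean distance between consecutive
#' changepoints, the heading runs from step start to step end, the
#' turning angle is the wrapped heading difference between consecutive
#' steps, and the feasible length `L` is obtained by ray-casting from the
#' step start along its heading to the boundary of the accessible region.
#'
#' @param changepoints output of [detect_changepoints()].
#' @param arena an [arena_geometry()] object.
#' @return steps tibble `tracklet_id`, `step`, `length`, `heading`,
#'   `turn` (NA for the first step of each tracklet), `start_x`,
#'   `start_y`, `feasible` (cm).
#' @export
steps_and_turns <- function(changepoints, arena = arena_geometry()) {
  changepoints |>
    dplyr::group_by(.data$tracklet_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) return(tibble::tibble())
      if (any(diff(d$cp) <= 0)) {
        stop("changepoints not strictly increasing in tracklet '",
             key$tracklet_id, "'")
      }
      dx <- diff(d$x); dy <- diff(d$y)
      len <- sqrt(dx^2 + dy^2)
      ok <- len > 0
      dx <- dx[ok]; dy <- dy[ok]; len <- len[ok]
      if (!length(len)) return(tibble::tibble())
      hd <- atan2(dy, dx)
      sx <- d$x[-nrow(d)][ok]; sy <- d$y[-nrow(d)][ok]
      L <- feasible_length(arena, sx, sy, hd)
      tibble::tibble(step = seq_along(len), length = len, heading = hd,
                     turn = c(NA_real_, wrap_angle(diff(hd))),
                     start_x = sx, start_y = sy,
                     feasible = pmax(L, len))
    }) |>
    dplyr::ungroup()
}
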