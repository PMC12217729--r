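#' Arena geometry for a two-comb observation hive
#'
#' Describes the accessible movement area of the queen as a union of
#' axis-aligned comb rectangles (cm, origin at the lower-left corner of the
#' accessible region, x rightward, y upward), together with the grid
#' conventions used by the spatial analyses and the queen's perceptive
#' radius.
#'
#' The default arena is two vertically stacked combs of 33.0 x 16.5 cm,
#' giving an almost-square 33 x 33 cm accessible region whose diagonal
#' (about 46.7 cm) is the longest possible straight-line motion.
#'
#' @param comb_rects data frame with columns `comb` (label), `xmin`,
#'   `ymin`, `xmax`, `ymax` in cm. Rectangles must not overlap.
#' @param perceptive_radius radius (cm) of the disc the queen is assumed
#'   to cover/influence around her position. Default 2.5.
#' @param heatmap_cell occupancy heatmap cell size (cm). Default 0.5.
#' @param flow_cell flow-map cell size (cm). Default 2.0.
#' @param coverage_cell areal-coverage grid cell size (cm). Default 0.1
#'   (a 1 mm grid).
#' @return an object of class `arena_geometry`.
#' @export
#' @examples
#' arena <- arena_geometry()
#' arena$diagonal
arena_geometry <- function(comb_rects = NULL,
                           perceptive_radius = 2.5,
                           heatmap_cell = 0.5,
                           flow_cell = 2.0,
                           coverage_cell = 0.1) {
  if (is.null(comb_rects)) {
    comb_rects <- tibble::tibble(
      comb = c("lower", "upper"),
      xmin = c(0, 0), ymin = c(0, 16.5),
      xmax = c(33, 33), ymax = c(16.5, 33)
    )
  }
  comb_rects <- tibble::as_tibble(comb_rects)
  stopifnot(all(c("comb", "xmin", "ymin", "xmax", "ymax") %in% names(comb_rects)),
            all(comb_rects$xmax > comb_rects$xmin),
            all(comb_rects$ymax > comb_rects$ymin),
            perceptive_radius > 0, heatmap_cell > 0,
            flow_cell > 0, coverage_cell > 0)
  if (nrow(comb_rects) > 1) {
    for (i in seq_len(nrow(comb_rects) - 1)) {
      for (j in seq(i + 1, nrow(comb_rects))) {
        ox <- min(comb_rects$xmax[c(i, j)]) - max(comb_rects$xmin[c(i, j)])
        oy <- min(comb_rects$ymax[c(i, j)]) - max(comb_rects$ymin[c(i, j)])
        if (ox > 1e-9 && oy > 1e-9) stop("comb rectangles overlap")
      }
    }
  }
  bbox <- c(xmin = min(comb_rects$xmin), ymin = min(comb_rects$ymin),
            xmax = max(comb_rects$xmax), ymax = max(comb_rects$ymax))
  structure(list(
    comb_rects = comb_rects,
    perceptive_radius = perceptive_radius,
    heatmap_cell = heatmap_cell,
    flow_cell = flow_cell,
    coverage_cell = coverage_cell,
    bbox = bbox,
    width = unname(bbox["xmax"] - bbox["xmin"]),
    height = unname(bbox["ymax"] - bbox["ymin"]),
    diagonal = unname(sqrt((bbox["xmax"] - bbox["xmin"])^2 +
                           (bbox["ymax"] - bbox["ymin"])^2))
  ), class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("<arena_geometry> ", nrow(x$comb_rects), " comb rectangle(s), ",
      sprintf("%.1f x %.1f cm, diagonal %.1f cm\n",
              x$width, x$height, x$diagonal), sep = "")
  cat("  perceptive radius ", x$perceptive_radius, " cm; cells: heatmap ",
      x$heatmap_cell, ", flow ", x$flow_cell, ", coverage ",
      x$coverage_cell, " cm\n", sep = "")
  invisible(x)
}

#' Test whether points lie inside the accessible region
#'
#' @param arena an [arena_geometry()] object.
#' @param x,y coordinates in cm.
#' @param tol boundary tolerance (cm); points within `tol` of a rectangle
#'   count as inside.
#' @return logical vector.
#' @export
arena_contains <- function(arena, x, y, tol = 1e-9) {
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(arena$comb_rects))) {
    r <- arena$comb_rects[i, ]
    inside <- inside | (x >= r$xmin - tol & x <= r$xmax + tol &
                        y >= r$ymin - tol & y <= r$ymax + tol)
  }
  inside
}

# clamp points into the accessible region (nearest point of nearest rect)
arena_clamp <- function(arena, x, y) {
  inside <- arena_contains(arena, x, y)
  if (all(inside)) return(cbind(x, y))
  idx <- which(!inside)
  rects <- arena$comb_rects
  for (k in idx) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(nrow(rects))) {
      cx <- min(max(x[k], rects$xmin[i]), rects$xmax[i])
      cy <- min(max(y[k], rects$ymin[i]), rects$ymax[i])
      d <- (cx - x[k])^2 + (cy - y[k])^2
      if (d < bd) { bd <- d; best <- c(cx, cy) }
    }
    x[k] <- best[1]; y[k] <- best[2]
  }
  cbind(x, y)
}

#' Feasible step length to the arena boundary
#'
#' Casts a ray from `(x, y)` along `heading` and returns the distance to
#' the point where the ray leaves the accessible region (the union of comb
#' rectangles). This is the maximal step length `L` available to a walker
#' at that position and orientation under confinement.
#'
#' @param arena an [arena_geometry()] object.
#' @param x,y ray origin (cm), inside the accessible region.
#' @param heading direction in radians (0 along +x, counter-clockwise).
#' @return numeric vector of feasible lengths (cm); 0 if the origin is on
#'   the boundary heading outward.
#' @export
feasible_length <- function(arena, x, y, heading) {
  n <- max(length(x), length(y), length(heading))
  x <- rep_len(x, n); y <- rep_len(y, n); heading <- rep_len(heading, n)
  vapply(seq_len(n), function(k) {
    ray_exit_distance(arena, x[k], y[k], cos(heading[k]), sin(heading[k]))
  }, numeric(1))
}

# distance along unit direction (dx, dy) at which the ray leaves the union
ray_exit_distance <- function(arena, x0, y0, dx, dy, tol = 1e-9) {
  rects <- arena$comb_rects
  tmax <- arena$width + arena$height + 1   # beyond any possible exit
  # candidate parameters: intersections with every rectangle edge line
  ts <- c(0)
  for (i in seq_len(nrow(rects))) {
    r <- rects[i, ]
    if (abs(dx) > tol) ts <- c(ts, (r$xmin - x0) / dx, (r$xmax - x0) / dx)
    if (abs(dy) > tol) ts <- c(ts, (r$ymin - y0) / dy, (r$ymax - y0) / dy)
  }
  ts <- sort(unique(ts[ts >= -tol & ts <= tmax]))
  ts <- c(ts, tmax)
  # walk the sorted breakpoints; the exit is the start of the first
  # interval whose midpoint is outside the union
  for (i in seq_len(length(ts) - 1)) {
    tm <- (ts[i] + ts[i + 1]) / 2
    if (!arena_contains(arena, x0 + tm * dx, y0 + tm * dy, tol = tol)) {
      return(max(0, ts[i]))
    }
  }
  tmax
}

#' Mirror a back-side tracklet to front-side coordinates
#'
#' The back side of a comb is viewed by its own camera; to pool both sides
#' the back view is flipped horizontally (`x' = width - x`), which is an
#' involution and preserves walked length exactly. The `side` label is
#' relabelled `"front"`.
#'
#' @param tracklets tibble in the tracklet dialect (columns `tracklet_id`,
#'   `hive`, `comb`, `side`, `t`, `x`, `y`).
#' @param arena an [arena_geometry()] object (supplies the arena width).
#' @return the tibble with back-side rows mirrored.
#' @export
flip_back_side <- function(tracklets, arena = arena_geometry()) {
  is_back <- tracklets$side == "back"
  if (!any(is_back)) {
    warning("no back-side samples; returning input unchanged")
    return(tracklets)
  }
  tracklets$x[is_back] <- arena$width - tracklets$x[is_back]
  tracklets$side[is_back] <- "front"
  tracklets
}
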