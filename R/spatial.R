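#' Occupancy heatmap of recorded time
#'
#' Each sample contributes its inter-sample dwell time (time to the next
#' sample of the same tracklet) to the grid cell it falls in, so the
#' total mass of the grid equals the total observed time.
#'
#' @param tracklets tracklet tibble.
#' @param arena an [arena_geometry()].
#' @param cell cell size (cm). Default the arena heatmap cell (0.5).
#' @return tibble `ix`, `iy`, `x`, `y` (cell centers), `seconds`.
#' @export
occupancy_heatmap <- function(tracklets, arena = arena_geometry(),
                              cell = NULL) {
  cell <- cell %||% arena$heatmap_cell
  d <- tracklets |>
    dplyr::group_by(.data$tracklet_id) |>
    dplyr::mutate(dt = c(diff(.data$t), 0)) |>
    dplyr::ungroup()
  d$ix <- floor((d$x - arena$bbox[["xmin"]]) / cell)
  d$iy <- floor((d$y - arena$bbox[["ymin"]]) / cell)
  d |>
    dplyr::group_by(.data$ix, .data$iy) |>
    dplyr::summarise(seconds = sum(.data$dt), .groups = "drop") |>
    dplyr::mutate(x = arena$bbox[["xmin"]] + (.data$ix + 0.5) * cell,
                  y = arena$bbox[["ymin"]] + (.data$iy + 0.5) * cell)
}

#' Orientation distribution while walking
#'
#' Headings of consecutive displacements larger than `min_disp`,
#' restricted to walking samples when states are available (back sides
#' are assumed already flipped by [read_tracklets()]). Angles use the
#' convention 0 along +x, counter-clockwise positive.
#'
#' @param tracklets tracklet tibble.
#' @param min_disp displacement filter (cm). Default 0.05.
#' @return tibble with a `heading` column (radians in `(-pi, pi]`).
#' @export
orientation_distribution <- function(tracklets, min_disp = 0.05) {
  hs <- heading_series(tracklets, min_disp)
  if ("state" %in% names(hs)) {
    hs <- dplyr::filter(hs, .data$state == "walking")
  }
  tibble::tibble(heading = hs$heading)
}

#' Per-cell flow map of movement directions
#'
#' Circular mean direction and mean resultant length of the movement
#' headings whose segment start falls in each cell of a coarse grid.
#' Cells with fewer than `min_count` headings are masked.
#'
#' @param tracklets tracklet tibble.
#' @param arena an [arena_geometry()].
#' @param cell cell size (cm). Default the arena flow cell (2).
#' @param min_count minimal headings per cell. Default 20.
#' @param min_disp displacement filter passed to [heading_series()].
#' @return tibble of class `flow_map`: `ix`, `iy`, `x`, `y`, `n`,
#'   `direction` (radians), `resultant` (in `[0, 1]`), `included`.
#' @export
flow_map <- function(tracklets, arena = arena_geometry(), cell = NULL,
                     min_count = 20, min_disp = 0.05) {
  cell <- cell %||% arena$flow_cell
  hs <- heading_series(tracklets, min_disp)
  if ("state" %in% names(hs)) {
    hs <- dplyr::filter(hs, .data$state == "walking")
  }
  hs$ix <- floor((hs$x - arena$bbox[["xmin"]]) / cell)
  hs$iy <- floor((hs$y - arena$bbox[["ymin"]]) / cell)
  out <- hs |>
    dplyr::group_by(.data$ix, .data$iy) |>
    dplyr::summarise(
      n = dplyr::n(),
      direction = atan2(mean(sin(.data$heading)),
                        mean(cos(.data$heading))),
      resultant = sqrt(mean(cos(.data$heading))^2 +
                         mean(sin(.data$heading))^2),
      .groups = "drop") |>
    dplyr::mutate(
      x = arena$bbox[["xmin"]] + (.data$ix + 0.5) * cell,
      y = arena$bbox[["ymin"]] + (.data$iy + 0.5) * cell,
      included = .data$n >= min_count)
  structure(out, cell = cell, class = c("flow_map", class(out)))
}

# neighbor pair list (undirected, i < j) for cells at integer (ix, iy)
neighbor_pairs <- function(ix, iy, neighborhood = "rook", radius = NULL,
                           cell = 1) {
  n <- length(ix)
  pairs <- which(outer(seq_len(n), seq_len(n), `<`), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  dx <- abs(ix[i] - ix[j]); dy <- abs(iy[i] - iy[j])
  keep <- switch(neighborhood,
    rook = (dx + dy) == 1,
    queen = pmax(dx, dy) == 1,
    radius = {
      stopifnot(!is.null(radius))
      d <- sqrt((dx * cell)^2 + (dy * cell)^2)
      d > 0 & d <= radius
    },
    stop("unknown neighborhood '", neighborhood, "'"))
  cbind(i = i[keep], j = j[keep])
}

#' Generalized directional Moran's I with permutation p-value
#'
#' Each unmasked cell direction is represented as a unit vector `u_i`;
#' deviations `x_i = u_i - mean(u)` (the circular-mean vector) enter
#'
#' `I = (n / W) * sum_ij w_ij (x_i . x_j) / sum_i (x_i . x_i)`
#'
#' with binary neighbor weights `w_ij` (rook 4-adjacency by default,
#' queen 8-adjacency and radius variants available) and
#' `W = sum_ij w_ij`. The p-value is permutation-based:
#' `p = (1 + #(I_perm >= I_obs)) / (1 + n_perm)` under random relabeling
#' of the cell directions. `I` is invariant to a global rotation of all
#' directions, since dot products of deviations are rotation-invariant.
#'
#' @param flow a [flow_map()] tibble (only rows with `included = TRUE`
#'   are used), or any tibble with `ix`, `iy`, `direction` columns.
#' @param neighborhood `"rook"`, `"queen"` or `"radius"`.
#' @param radius neighborhood radius (cm) for `"radius"`.
#' @param n_perm permutations. Default 10000.
#' @param seed RNG seed (required: the permutation null is stochastic).
#' @return object of class `morans_result`: `I`, `p_value`, `n_perm`,
#'   `n_cells`, `neighborhood`, `expectation` (`-1/(n-1)`).
#' @export
morans_directional <- function(flow, neighborhood = c("rook", "queen",
                                                      "radius"),
                               radius = NULL, n_perm = 10000, seed = 1) {
  neighborhood <- match.arg(neighborhood)
  d <- flow
  if ("included" %in% names(d)) d <- d[d$included, ]
  n <- nrow(d)
  if (n < 10) stop("need at least 10 unmasked cells, got ", n)
  U <- cbind(cos(d$direction), sin(d$direction))
  X <- sweep(U, 2, colMeans(U))
  denom <- sum(X^2)
  if (denom < 1e-12) {
    stop("all cell directions identical; Moran's I undefined")
  }
  cellsz <- attr(flow, "cell") %||% 1
  pr <- neighbor_pairs(d$ix, d$iy, neighborhood, radius, cellsz)
  if (!nrow(pr)) stop("no neighboring cell pairs under this neighborhood")
  W <- 2 * nrow(pr)                      # symmetric weights
  i <- pr[, 1]; j <- pr[, 2]
  I_of <- function(M) {
    num <- 2 * sum(M[i, 1] * M[j, 1] + M[i, 2] * M[j, 2])
    (n / W) * num / sum(M^2)
  }
  I_obs <- I_of(X)
  set.seed(seed)
  I_perm <- vapply(seq_len(n_perm), function(b) {
    I_of(X[sample.int(n), , drop = FALSE])
  }, numeric(1))
  p <- (1 + sum(I_perm >= I_obs)) / (1 + n_perm)
  structure(list(I = I_obs, p_value = p, n_perm = n_perm, n_cells = n,
                 neighborhood = neighborhood,
                 expectation = -1 / (n - 1)),
            class = "morans_result")
}

#' @export
print.morans_result <- function(x, ...) {
  cat(sprintf(
    "<morans_result> I = %.4f (E[I] = %.4f under the null), p = %.4g (%s, %d cells, %d permutations)\n",
    x$I, x$expectation, x$p_value, x$neighborhood, x$n_cells, x$n_perm))
  invisible(x)
}
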