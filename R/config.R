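#' Load analysis configuration from YAML
#'
#' Reads a YAML file whose top-level blocks override the package
#' defaults: `arena` (with `comb_rects`, `perceptive_radius`,
#' `heatmap_cell`, `flow_cell`, `coverage_cell`), `activity`
#' (see [activity_params()]), `changepoints` (see
#' [changepoint_params()]) and `synthetic` (see [synthetic_config()];
#' requires a `seed`). Missing blocks fall back to defaults.
#'
#' @param path YAML file path.
#' @return list with elements `arena`, `activity`, `changepoints` and
#'   (if configured) `synthetic`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("arena:", "  perceptive_radius: 3.0",
#'              "changepoints:", "  window: 1.0"), f)
#' cfg <- load_config(f)
#' cfg$arena$perceptive_radius
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  arena_args <- raw$arena %||% list()
  if (!is.null(arena_args$comb_rects)) {
    arena_args$comb_rects <-
      dplyr::bind_rows(lapply(arena_args$comb_rects, tibble::as_tibble))
  }
  out <- list(
    arena = do.call(arena_geometry, arena_args),
    activity = do.call(activity_params, raw$activity %||% list()),
    changepoints = do.call(changepoint_params,
                           raw$changepoints %||% list())
  )
  if (!is.null(raw$synthetic)) {
    syn <- raw$synthetic
    syn$arena <- out$arena
    if (!is.null(syn$step_params)) syn$step_params <- unlist(syn$step_params)
    out$synthetic <- do.call(synthetic_config, syn)
  }
  out
}
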