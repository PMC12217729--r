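#' Run the full analysis pipeline
#'
#' Orchestrates preprocessing (smoothing, activity segmentation),
#' changepoint detection and step extraction, ensemble metrics, spatial
#' statistics, model fitting on the training sample and (optionally) the
#' matched simulation comparison, from a tracklet tibble or a synthetic
#' configuration. Every stochastic stage receives a seed derived
#' deterministically from the global seed, so a re-run with the same
#' inputs reproduces every number.
#'
#' @param input tracklet tibble, a path to a tracklet CSV, or a
#'   [synthetic_config()].
#' @param arena an [arena_geometry()].
#' @param seed global seed.
#' @param families tail families to compare. Default all five.
#' @param simulate run the matched-ensemble comparison for the
#'   best-weighted family. Default TRUE.
#' @param out_dir optional directory for JSON results
#'   (see [write_results()]).
#' @param min_obs curve clipping threshold. Default 30.
#' @return list of class `queenwalk_pipeline` with elements `tracklets`,
#'   `steps`, `curves`, `flow`, `morans`, `fits`, `vonmises`, `body`,
#'   `simulation`, `manifest`.
#' @export
run_pipeline <- function(input, arena = arena_geometry(), seed = 1,
                         families = tail_family_names, simulate = TRUE,
                         out_dir = NULL, min_obs = 30) {
  if (inherits(input, "synthetic_config")) {
    tracklets <- generate_synthetic(input)$observed
  } else if (is.character(input)) {
    tracklets <- read_tracklets(input, arena)
  } else {
    tracklets <- input
  }
  sm <- kalman_smooth(tracklets, arena = arena)
  seg <- segment_activity(sm)
  cps <- detect_changepoints(seg)
  steps <- steps_and_turns(cps, arena)
  curves <- list(
    diffusivity = diffusivity_curve(seg, min_obs = min_obs),
    mfp = mfp_curve(seg, min_obs = min_obs),
    coverage = coverage_curve(seg, arena, min_obs = min_obs),
    selfcross = selfcross_curve(seg, min_obs = min_obs))
  flow <- flow_map(seg, arena)
  morans <- tryCatch(
    morans_directional(flow, seed = derive_seed(seed, "morans")),
    error = function(e) e$message)
  train <- tryCatch(suppressWarnings(training_sample(seg)),
                    error = function(e) seg)
  train_steps <- steps_and_turns(detect_changepoints(train), arena)
  vm <- tryCatch(fit_vonmises(train_steps$turn), error = function(e) NULL)
  fits <- tryCatch(compare_families(train_steps, families),
                   error = function(e) NULL)
  body <- if (!is.null(fits)) {
    fit_body(train_steps, fits$fit[[1]]$l_min)
  }
  simres <- NULL
  if (simulate && !is.null(fits) && !is.null(vm)) {
    model <- walk_model(vm, fits$fit[[1]], body, arena)
    sim <- simulate_matched_ensemble(model, seg,
                                     seed = derive_seed(seed, "sim"))
    simres <- compare_to_empirical(sim, curves, arena, min_obs = min_obs)
  }
  manifest <- list(seed = seed, n_samples = nrow(tracklets),
                   n_tracklets = length(unique(tracklets$tracklet_id)),
                   families = families,
                   arena = arena$comb_rects)
  out <- structure(list(tracklets = seg, steps = steps, curves = curves,
                        flow = flow, morans = morans, fits = fits,
                        vonmises = vm, body = body, simulation = simres,
                        manifest = manifest),
                   class = "queenwalk_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (k in names(curves)) {
      write_results(curves[[k]], file.path(out_dir, paste0(k, ".json")),
                    parameters = list(min_obs = min_obs), seed = seed)
    }
    if (!is.null(fits)) {
      write_results(dplyr::select(fits, -"fit"),
                    file.path(out_dir, "fits.json"), seed = seed)
    }
    write_results(manifest, file.path(out_dir, "manifest.json"),
                  seed = seed)
  }
  out
}

#' @export
print.queenwalk_pipeline <- function(x, ...) {
  cat("<queenwalk_pipeline> ", x$manifest$n_tracklets, " tracklets, ",
      nrow(x$steps), " steps\n", sep = "")
  if (!is.null(x$fits)) {
    cat("  best tail family: ", x$fits$family[1],
        sprintf(" (Akaike weight %.3f)\n", x$fits$akaike_weight[1]),
        sep = "")
  }
  invisible(x)
}
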