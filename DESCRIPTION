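Package: queenwalk
Title: Movement Analysis of Honeybee Queens in Confined Comb Arenas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-frequency (10 Hz) positional
    tracking of honeybee queens confined to a two-comb observation arena.
    Provides tracklet input/output and Kalman smoothing, activity
    segmentation into walking, resting and short-stop states,
    eigenvalue-ratio changepoint detection yielding step-and-turn series,
    ensemble spatial-dynamics metrics (diffusivity, mean first passage,
    areal coverage, self-crossing, box-counting fractal dimension) with
    theoretical bounds and power-model fits, occupancy and flow maps with
    a permutation-tested directional Moran's I, confinement-aware maximum
    likelihood fitting of turning-angle and step-length distributions
    (exponential, squared-exponential, Pareto, truncated and
    exponentially truncated Pareto tails with KS-based tail-start
    selection, AIC comparison and bootstrap), confined step-and-turn
    walker simulation, and a ground-truth-labelled synthetic data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
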