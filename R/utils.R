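#' @importFrom mclust Mclust mclustBIC
#' @importFrom rlang .data :=
#' @importFrom stats optim optimize uniroot sd quantile median var coef lm
#'   nls integrate runif rnorm rexp rbinom approx ecdf pchisq setNames
#'   complete.cases
#' @importFrom utils head tail
NULL

#' Wrap angles to the interval (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to `(-pi, pi]`.
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # %% maps pi to -pi; keep the convention half-open at -pi
  out[out == -pi] <- pi
  out
}

#' Circular mean and mean resultant length
#'
#' @param theta angles in radians.
#' @return list with `mean` (radians, in `(-pi, pi]`) and `R` (mean
#'   resultant length in `[0, 1]`).
#' @export
circular_mean <- function(theta) {
  C <- mean(cos(theta))
  S <- mean(sin(theta))
  list(mean = atan2(S, C), R = sqrt(C^2 + S^2))
}

# cumulative walked (arc) length of a polyline given x, y
walked_length <- function(x, y) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
}

# deterministic per-stage seed derivation; keeps values < 2^31
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
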