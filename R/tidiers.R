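#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a von Mises fit
#'
#' @param x a `vonmises_fit`.
#' @param ... unused.
#' @return one-row tibble of parameter estimates.
#' @export
tidy.vonmises_fit <- function(x, ...) {
  tibble::tibble(term = c("rho", "kappa"),
                 estimate = c(x$rho, x$kappa))
}

#' @rdname tidy.vonmises_fit
#' @export
glance.vonmises_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logL, n = x$n, R = x$R, capped = x$capped)
}

#' Tidy a step-length tail fit
#'
#' @param x a `tail_fit`.
#' @param ... unused.
#' @return tibble of parameter estimates.
#' @export
tidy.tail_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.tail_fit
#' @export
glance.tail_fit <- function(x, ...) {
  tibble::tibble(family = x$family, l_min = x$l_min, logLik = x$logL,
                 AIC = x$AIC, ks_distance = x$ks_distance,
                 akaike_weight = x$akaike_weight, n_tail = x$n_tail,
                 n_dropped = x$n_dropped, converged = x$converged)
}

#' Tidy a metric curve
#'
#' @param x a `metric_curve`.
#' @param ... unused.
#' @return the curve as a plain tibble.
#' @export
tidy.metric_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.metric_curve
#' @export
glance.metric_curve <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble::tibble(kind = attr(x, "kind"),
                 a = fit$a %||% NA_real_, b = fit$b %||% NA_real_,
                 c = fit$c %||% NA_real_, r2 = fit$r2 %||% NA_real_)
}

#' Tidy a Moran's I permutation result
#'
#' @param x a `morans_result`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
tidy.morans_result <- function(x, ...) {
  tibble::tibble(statistic = x$I, p.value = x$p_value,
                 expectation = x$expectation, n_cells = x$n_cells,
                 n_perm = x$n_perm, neighborhood = x$neighborhood)
}

#' Tidy a daily short-stop uniformity test
#'
#' @param x a `stop_uniformity`.
#' @param ... unused.
#' @return the hourly mean-rate tibble.
#' @export
tidy.stop_uniformity <- function(x, ...) {
  x$hourly
}

#' @rdname tidy.stop_uniformity
#' @export
glance.stop_uniformity <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 mean_rate = x$mean_rate, ci_low = x$ci[1],
                 ci_high = x$ci[2], n_tracklets = x$n_tracklets)
}

#' Tidy a fractal-dimension estimate
#'
#' @param x a `fractal_estimate`.
#' @param ... unused.
#' @return tibble of box sizes and counts.
#' @export
tidy.fractal_estimate <- function(x, ...) {
  tibble::tibble(box_size = x$box_sizes, box_count = x$box_counts)
}

#' @rdname tidy.fractal_estimate
#' @export
glance.fractal_estimate <- function(x, ...) {
  tibble::tibble(dimension = x$dimension, sd = x$sd,
                 n_scales = length(x$box_sizes))
}
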