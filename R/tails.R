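#' Step-length tail families
#'
#' Five candidate families for the tail of the step-length distribution
#' on `[l_min, Inf)` (or `[l_min, b]` for the truncated Pareto):
#'
#' * `exponential`: `f(l) = lambda * exp(-lambda * (l - l_min))`
#' * `squared_exponential`: `f(l) ~ exp(-(l / sigma)^2)`
#' * `pareto`: `f(l) = (mu - 1) / l_min * (l / l_min)^-mu`, `mu > 1`
#' * `truncated_pareto`: `f(l) ~ l^-mu` on `[l_min, b]`
#' * `exp_truncated_pareto`: `f(l) ~ l^-mu * exp(-lambda * l)`
#'
#' All densities are normalized on their support; `ptail`/`qtail` give the
#' corresponding CDF and quantile function, `rtail` samples.
#'
#' @name tail_families
NULL

tail_family_names <- c("exponential", "squared_exponential", "pareto",
                       "truncated_pareto", "exp_truncated_pareto")

erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
erfc <- function(z) 2 * stats::pnorm(-z * sqrt(2))
erfinv <- function(z) stats::qnorm((z + 1) / 2) / sqrt(2)

# upper incomplete gamma Gamma(a, x) for any real a, x > 0;
# recurrence Gamma(a, x) = (Gamma(a + 1, x) - x^a e^-x) / a lifts a > 0
gamma_inc_upper <- function(a, x) {
  if (a > 0) return(gamma(a) * stats::pgamma(x, a, lower.tail = FALSE))
  k <- ceiling(-a) + 1          # shift into (0, 1]
  a0 <- a + k
  g <- gamma(a0) * stats::pgamma(x, a0, lower.tail = FALSE)
  for (i in seq_len(k)) {
    ai <- a0 - i
    g <- (g - x^(ai) * exp(-x)) / ai
  }
  g
}

check_family <- function(family) {
  match.arg(family, tail_family_names)
}

#' @rdname tail_families
#' @param l,q,u,n lengths (cm), quantiles, uniform variates, sample size.
#' @param family one of `"exponential"`, `"squared_exponential"`,
#'   `"pareto"`, `"truncated_pareto"`, `"exp_truncated_pareto"`.
#' @param params named numeric vector of family parameters (`lambda`,
#'   `sigma`, `mu`, `b` as applicable).
#' @param l_min lower end of the tail support (cm).
#' @param log return log density.
#' @return density, probability, quantile or sample vector.
#' @export
dtail <- function(l, family, params, l_min, log = FALSE) {
  family <- check_family(family)
  ld <- rep(-Inf, length(l))
  inside <- l >= l_min
  switch(family,
    exponential = {
      lam <- params[["lambda"]]
      ld[inside] <- base::log(lam) - lam * (l[inside] - l_min)
    },
    squared_exponential = {
      sg <- params[["sigma"]]
      Z <- sg * sqrt(pi) / 2 * erfc(l_min / sg)
      ld[inside] <- -(l[inside] / sg)^2 - base::log(Z)
    },
    pareto = {
      mu <- params[["mu"]]
      ld[inside] <- base::log(mu - 1) - base::log(l_min) -
        mu * (base::log(l[inside]) - base::log(l_min))
    },
    truncated_pareto = {
      mu <- params[["mu"]]; b <- params[["b"]]
      inside <- inside & l <= b
      ld <- rep(-Inf, length(l))
      Z <- pareto_seg_mass(l_min, b, mu)
      ld[inside] <- -mu * base::log(l[inside]) - base::log(Z)
    },
    exp_truncated_pareto = {
      mu <- params[["mu"]]; lam <- params[["lambda"]]
      Z <- lam^(mu - 1) * gamma_inc_upper(1 - mu, lam * l_min)
      ld[inside] <- -mu * base::log(l[inside]) - lam * l[inside] -
        base::log(Z)
    })
  if (log) ld else exp(ld)
}

# integral of l^-mu on [lo, hi] (handles mu = 1)
pareto_seg_mass <- function(lo, hi, mu) {
  if (abs(mu - 1) < 1e-9) return(base::log(hi / lo))
  (hi^(1 - mu) - lo^(1 - mu)) / (1 - mu)
}

#' @rdname tail_families
#' @export
ptail <- function(q, family, params, l_min) {
  family <- check_family(family)
  p <- numeric(length(q))
  above <- q > l_min
  switch(family,
    exponential = {
      lam <- params[["lambda"]]
      p[above] <- 1 - exp(-lam * (q[above] - l_min))
    },
    squared_exponential = {
      sg <- params[["sigma"]]
      p[above] <- (erf(q[above] / sg) - erf(l_min / sg)) / erfc(l_min / sg)
    },
    pareto = {
      mu <- params[["mu"]]
      p[above] <- 1 - (q[above] / l_min)^(1 - mu)
    },
    truncated_pareto = {
      mu <- params[["mu"]]; b <- params[["b"]]
      qq <- pmin(q[above], b)
      p[above] <- vapply(qq, function(h) pareto_seg_mass(l_min, h, mu),
                         numeric(1)) / pareto_seg_mass(l_min, b, mu)
    },
    exp_truncated_pareto = {
      mu <- params[["mu"]]; lam <- params[["lambda"]]
      g0 <- gamma_inc_upper(1 - mu, lam * l_min)
      gq <- vapply(lam * q[above], function(x) gamma_inc_upper(1 - mu, x),
                   numeric(1))
      p[above] <- 1 - gq / g0
    })
  pmin(pmax(p, 0), 1)
}

#' @rdname tail_families
#' @export
qtail <- function(u, family, params, l_min) {
  family <- check_family(family)
  switch(family,
    exponential = l_min - base::log(1 - u) / params[["lambda"]],
    squared_exponential = {
      sg <- params[["sigma"]]
      sg * erfinv(erf(l_min / sg) + u * erfc(l_min / sg))
    },
    pareto = l_min * (1 - u)^(-1 / (params[["mu"]] - 1)),
    truncated_pareto = {
      mu <- params[["mu"]]; b <- params[["b"]]
      Z <- pareto_seg_mass(l_min, b, mu)
      if (abs(mu - 1) < 1e-9) {
        l_min * exp(u * Z)
      } else {
        (l_min^(1 - mu) + u * Z * (1 - mu))^(1 / (1 - mu))
      }
    },
    exp_truncated_pareto = qtail_numeric(u, family, params, l_min))
}

# monotone-grid inversion for families without a closed-form quantile
qtail_numeric <- function(u, family, params, l_min, n_grid = 4096) {
  hi <- l_min
  while (ptail(hi, family, params, l_min) < max(min(max(u), 1 - 1e-12),
                                                0.5)) {
    hi <- hi * 2
    if (hi > 1e9) break
  }
  grid <- exp(seq(base::log(l_min), base::log(hi * 2), length.out = n_grid))
  cdf <- ptail(grid, family, params, l_min)
  keep <- !duplicated(cdf)
  stats::approx(cdf[keep], grid[keep], xout = u, rule = 2)$y
}

#' @rdname tail_families
#' @export
rtail <- function(n, family, params, l_min) {
  qtail(stats::runif(n), family, params, l_min)
}

n_tail_params <- function(family, fit_b = FALSE) {
  switch(check_family(family),
         exponential = 1, squared_exponential = 1, pareto = 1,
         truncated_pareto = if (fit_b) 2 else 1,
         exp_truncated_pareto = 2)
}

# parameter transforms: unconstrained theta <-> named params
tail_theta_to_params <- function(theta, family, l_min, max_l, b_max) {
  switch(check_family(family),
    exponential = c(lambda = exp(theta[1])),
    squared_exponential = c(sigma = exp(theta[1])),
    pareto = c(mu = 1 + exp(theta[1])),
    truncated_pareto = if (length(theta) >= 2) {
      bm <- max(b_max, max_l * 1.001)
      c(mu = exp(theta[1]),
        b = max_l + stats::plogis(theta[2]) * (bm - max_l))
    } else {
      c(mu = exp(theta[1]), b = b_max)    # upper bound fixed at b_max
    },
    exp_truncated_pareto = c(mu = exp(theta[1]), lambda = exp(theta[2])))
}

tail_start_theta <- function(family, l, l_min, b_max, fit_b = FALSE) {
  m <- mean(l - l_min)
  switch(check_family(family),
    exponential = base::log(1 / max(m, 1e-6)),
    squared_exponential = base::log(sqrt(mean(l^2))),
    pareto = {
      mu_hill <- 1 + 1 / max(mean(base::log(l / l_min)), 1e-6)
      base::log(max(mu_hill - 1, 0.05))
    },
    truncated_pareto = if (fit_b) c(base::log(1.5), 0) else base::log(1.5),
    exp_truncated_pareto = c(base::log(0.5), base::log(1 / max(m, 1e-6))))
}
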