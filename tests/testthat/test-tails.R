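# family parameter sets used across the tail tests
tail_cases <- list(
  exponential = c(lambda = 1.3),
  squared_exponential = c(sigma = 1),
  pareto = c(mu = 2.2),
  truncated_pareto = c(mu = 2.2, b = 10),
  exp_truncated_pareto = c(mu = 1.5, lambda = 0.5)
)

test_that("tail densities integrate to 1 on their support", {
  for (fam in names(tail_cases)) {
    par <- tail_cases[[fam]]
    for (lmin in c(0.1, 0.5, 2)) {
      upper <- if (fam == "truncated_pareto") par[["b"]] else Inf
      if (upper <= lmin) next
      Z <- stats::integrate(function(l) dtail(l, fam, par, lmin),
                            lmin, upper, rel.tol = 1e-9)$value
      expect_equal(Z, 1, tolerance = 1e-6,
                   label = paste(fam, "l_min", lmin))
    }
  }
})

test_that("ptail matches numeric integration and qtail inverts it", {
  for (fam in names(tail_cases)) {
    par <- tail_cases[[fam]]
    qs <- c(0.6, 1.1, 2.4, 6)
    if (fam == "truncated_pareto") qs <- qs[qs < par[["b"]]]
    direct <- vapply(qs, function(q) {
      stats::integrate(function(l) dtail(l, fam, par, 0.5), 0.5, q,
                       rel.tol = 1e-9)$value
    }, numeric(1))
    expect_equal(ptail(qs, fam, par, 0.5), direct, tolerance = 1e-5,
                 label = fam)
    u <- c(0.05, 0.3, 0.7, 0.95)
    back <- ptail(qtail(u, fam, par, 0.5), fam, par, 0.5)
    expect_equal(back, u, tolerance = 1e-3, label = fam)
  }
})

test_that("unconfined MLE recovers generating parameters", {
  set.seed(21)
  recov <- list(
    exponential = c("lambda", 1.3, 0.04),
    pareto = c("mu", 2.2, 0.05),
    squared_exponential = c("sigma", 1.0, 0.02)
  )
  for (fam in names(recov)) {
    pn <- recov[[fam]][1]
    truth <- as.numeric(recov[[fam]][2])
    tol <- as.numeric(recov[[fam]][3])
    x <- rtail(1e4, fam, tail_cases[[fam]], 0.5)
    f <- fit_tail(x, fam, 0.5)
    expect_equal(unname(f$params[[pn]]), truth, tolerance = tol / truth,
                 label = fam)
    expect_true(f$converged)
  }
  # truncated Pareto: fixed-bound default and fitted-bound variant
  x <- rtail(2e4, "truncated_pareto", c(mu = 2.2, b = 10), 0.5)
  f <- fit_tail(x, "truncated_pareto", 0.5, b_max = 10)
  expect_equal(unname(f$params[["mu"]]), 2.2, tolerance = 0.05)
  ff <- fit_tail(x, "truncated_pareto", 0.5, b_max = 47, fit_b = TRUE)
  expect_equal(unname(ff$params[["mu"]]), 2.2, tolerance = 0.05)
  expect_equal(unname(ff$params[["b"]]), 10, tolerance = 0.05)
  # data beyond a fixed bound make the family infeasible
  fi <- fit_tail(rtail(200, "pareto", c(mu = 2.2), 0.5),
                 "truncated_pareto", 0.5, b_max = 5, n_tail_min = 50)
  expect_false(fi$converged)
  expect_equal(fi$AIC, Inf)
  x <- rtail(2e4, "exp_truncated_pareto", c(mu = 1.5, lambda = 0.5), 0.5)
  f <- fit_tail(x, "exp_truncated_pareto", 0.5)
  expect_equal(unname(f$params[["mu"]]), 1.5, tolerance = 0.1)
  expect_equal(unname(f$params[["lambda"]]), 0.5, tolerance = 0.15)
})

test_that("confined MLE is unbiased where the naive MLE is not", {
  set.seed(22)
  # heavily confined: every feasible length is 2 cm
  L <- 2
  lam <- 1.3
  u <- runif(2e4) * ptail(L, "exponential", c(lambda = lam), 0.1)
  l <- qtail(u, "exponential", c(lambda = lam), 0.1)
  steps <- tibble::tibble(length = l, feasible = L)
  conf <- fit_tail(steps, "exponential", 0.1)
  naive <- fit_tail(l, "exponential", 0.1)
  se <- lam / sqrt(length(l))
  expect_lt(abs(conf$params[["lambda"]] - lam), 4 * se)
  expect_gt(naive$params[["lambda"]] - lam, 10 * se)  # strongly biased up
})

test_that("fit_tail agrees with an independent grid-search maximizer", {
  set.seed(23)
  x <- rtail(800, "exponential", c(lambda = 1.3), 0.5)
  grid <- seq(0.8, 2.0, by = 0.0005)
  expect_equal(unname(fit_tail(x, "exponential", 0.5)$params[["lambda"]]),
               grid_mle_tail(x, "exponential", 0.5, grid),
               tolerance = 2e-3)
  y <- rtail(800, "pareto", c(mu = 2.2), 0.5)
  gridm <- seq(1.5, 3.5, by = 0.0005)
  expect_equal(unname(fit_tail(y, "pareto", 0.5)$params[["mu"]]),
               grid_mle_tail(y, "pareto", 0.5, gridm),
               tolerance = 2e-3)
})

test_that("scan_lmin finds the tail start by KS distance", {
  set.seed(24)
  # body below 1 cm + clean Pareto tail above 1 cm
  body <- runif(3000, 0.05, 1)
  tail_x <- rtail(3000, "pareto", c(mu = 2.2), 1.0)
  f <- scan_lmin(c(body, tail_x), "pareto")
  scan <- attr(f, "scan")
  gridstep <- median(diff(sort(unique(scan$l_min))))
  expect_lt(abs(f$l_min - 1.0), 3 * gridstep + 0.1)
  expect_equal(unname(f$params[["mu"]]), 2.2, tolerance = 0.1)
  # selected KS is minimal across the scan (by construction, asserted)
  expect_true(all(f$ks_distance <= scan$ks_distance + 1e-12))
  # pure exponential data: KS-optimal l_min near the low end of the grid
  xe <- rtail(4000, "exponential", c(lambda = 1.3), 0.05)
  fe <- scan_lmin(xe, "exponential")
  expect_lt(fe$l_min, stats::quantile(xe, 0.3))
  # too few steps
  expect_error(scan_lmin(rexp(5), "exponential"), "l_min|observations")
})

test_that("akaike weights follow the exp(-delta/2) rule", {
  set.seed(25)
  x <- rtail(3000, "exponential", c(lambda = 1.3), 0.5)
  fits <- lapply(c("exponential", "squared_exponential", "pareto"),
                 function(f) fit_tail(x, f, 0.5))
  w <- akaike_weights(fits)
  ws <- vapply(w, function(f) f$akaike_weight, numeric(1))
  expect_equal(sum(ws), 1)
  expect_equal(w[[1]]$akaike_weight, max(ws))   # truth wins here
  # equal AICs -> equal weights
  f2 <- fits[1:2]; f2[[2]]$AIC <- f2[[1]]$AIC
  ws2 <- vapply(akaike_weights(f2), function(f) f$akaike_weight,
                numeric(1))
  expect_equal(ws2, c(0.5, 0.5))
  # delta AIC of 20 -> loser weight < 1e-4
  f3 <- fits[1:2]; f3[[2]]$AIC <- f3[[1]]$AIC + 20
  ws3 <- vapply(akaike_weights(f3), function(f) f$akaike_weight,
                numeric(1))
  expect_lt(ws3[2], 1e-4)
  # fits on different supports refused
  fd <- list(fit_tail(x, "exponential", 0.5),
             fit_tail(x, "exponential", 1.0))
  expect_error(akaike_weights(fd), "different data")
})

test_that("bootstrap_params is seeded and calibrated on clean data", {
  set.seed(26)
  x <- tibble::tibble(length = rtail(1500, "exponential",
                                     c(lambda = 1.3), 0.3))
  b1 <- bootstrap_params(x, "exponential", B = 30, seed = 5)
  b2 <- bootstrap_params(x, "exponential", B = 30, seed = 5)
  expect_identical(b1$mean, b2$mean)
  expect_true(all(b1$sd > 0))
  lam <- b1[b1$parameter == "lambda", ]
  expect_lt(abs(lam$mean - 1.3), 3 * lam$sd + 0.05)
})

test_that("fit_body captures sub-l_min mass and scale", {
  set.seed(27)
  steps <- c(runif(300, 0, 1), rtail(700, "exponential",
                                     c(lambda = 1.3), 1))
  bf <- fit_body(steps, 1.0)
  expect_equal(bf$mass, 0.3, tolerance = 1e-12)
  expect_true(bf$scale > 0)
  # all steps above l_min -> zero mass
  bf0 <- fit_body(rtail(200, "exponential", c(lambda = 1), 1), 0.5)
  expect_equal(bf0$mass, 0)
  # sample concentrated just below l_min -> small fitted scale
  near <- 1 - abs(rnorm(500, 0, 0.02))
  bfn <- fit_body(near, 1.0)
  expect_lt(bfn$scale, 0.1)
})
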