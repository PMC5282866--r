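test_that("Poisson count pmf and expected counts", {
  expect_equal(count_log_pmf(0, 2.5), -2.5)
  expect_equal(count_log_pmf(2, 1), log(exp(-1) / 2), tolerance = 1e-12)
  expect_identical(count_log_pmf(3, 0), -Inf)
  expect_error(count_log_pmf(-1, 1), "non-negative")

  m <- duplicate_model(3, 1.5, 0.4)
  expect_equal(expected_count(m, 680, 0), 680, tolerance = 1e-10)
  p_S <- unname(absorption_probabilities(m)["p_S"])
  expect_equal(expected_count(m, 680, 100), 680 * p_S, tolerance = 1e-6)
  ec <- expected_count(m, duplication_model(680), seq(0, 3, by = 0.2))
  expect_true(all(diff(ec) <= 0))
})

test_that("log-likelihood is the sum of per-bin Poisson masses", {
  set.seed(31)
  for (i in 1:4) {
    m <- rand_model(z = sample(2:6, 1))
    beta0 <- runif(1, 50, 500)
    n <- sample(5:30, 1)
    dat <- binned_counts(rpois(n, 20), bin_width = 0.02)
    mu <- beta0 * pseudo_survival(m, dat$s)
    expect_equal(log_likelihood(m, beta0, dat),
                 sum(count_log_pmf(dat$counts, mu)), tolerance = 1e-12)
  }

  m <- duplicate_model(2, 1, 1)
  expect_identical(log_likelihood(m, 10, binned_counts(integer(0))), 0)

  # additivity over disjoint bin sets
  d1 <- binned_counts(c(5L, 3L), s = c(0.01, 0.02))
  d2 <- binned_counts(c(2L, 1L), s = c(0.03, 0.04))
  dall <- binned_counts(c(5L, 3L, 2L, 1L), s = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(log_likelihood(m, 10, dall),
               log_likelihood(m, 10, d1) + log_likelihood(m, 10, d2),
               tolerance = 1e-12)
})

test_that("binned-count container validates its invariants", {
  expect_error(binned_counts(c(1, -2)), "non-negative")
  expect_error(binned_counts(c(1.5, 2)), "non-negative")
  expect_error(binned_counts(c(1L, 2L), s = c(0.2, 0.1)), "increasing")
  expect_error(binned_counts(c(1L, 2L), s = 0.1), "equal length")
  d <- binned_counts(c(4L, 0L, 2L))
  expect_equal(d$s, c(0.01, 0.02, 0.03))
})

test_that("truncated-Poisson z prior matches the direct finite sum", {
  pr <- z_prior(alpha = 1)
  # p_2 = (1/2!) / sum_{k=2}^{20} 1/k!  (alpha = 1, factors e^-a cancel)
  direct <- (1 / 2) / sum(1 / factorial(2:20))
  expect_equal(pr$weights[1], direct, tolerance = 1e-12)
  expect_equal(direct, 0.6961, tolerance = 1e-4)

  for (a in c(0.5, 1, 4, 15))
    expect_equal(sum(z_prior(alpha = a)$weights), 1, tolerance = 1e-12)

  # alpha -> 0 concentrates all mass at the lower truncation point
  expect_gt(z_prior(alpha = 1e-8)$weights[1], 1 - 1e-7)

  expect_error(z_prior(alpha = -1), "positive")
  expect_error(z_prior(z = 3, alpha = 1), "either")
  dg <- z_prior(z = 7)
  expect_identical(dg$support, 7L)
  expect_identical(dg$weights, 1)
})

test_that("MLE recovers informative synthetic truth at the true z", {
  truth <- list(z = 3, u_c = 20.07, u_r = 3.26, beta0 = 680.84)
  m <- duplicate_model(truth$z, truth$u_c, truth$u_r)
  dat <- simulate_counts(m, truth$beta0, n_bins = 100, seed = 404)
  fit <- fit_mle(dat, z_grid = 3, n_starts = 6, seed = 1)
  expect_equal(unname(fit$mle["u_c"]), truth$u_c, tolerance = 0.15)
  expect_equal(unname(fit$mle["beta0"]), truth$beta0, tolerance = 0.1)
  expect_equal(unname(fit$mle["u_r"]), truth$u_r, tolerance = 0.4)

  # stationarity: scaled numerical gradient vanishes at the optimum
  fn <- subfunr:::nll_factory(3, dat)
  par <- log(unname(fit$mle[c("u_r", "u_c", "beta0")]))
  g <- vapply(1:3, function(j) {
    h <- 1e-5
    e <- numeric(3); e[j] <- h
    (fn(par + e) - fn(par - e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g)) / max(1, abs(fn(par))), 1e-3)
})

test_that("z selection is an arg-max with near-ties reported", {
  m <- duplicate_model(3, 15, 2.5)
  dat <- simulate_counts(m, 300, n_bins = 60, seed = 17)
  fit <- fit_mle(dat, z_grid = 2:5, n_starts = 4, seed = 3)
  best <- fit$per_z$logLik[fit$per_z$z == fit$z_hat]
  expect_true(all(best >= fit$per_z$logLik - 1e-6))
  expect_true(fit$z_hat %in% fit$near_ties)
  expect_error(fit_mle(binned_counts(c(1L, 2L)), z_grid = 2),
               "at least 3 bins")
})

test_that("data simulated without regulatory mutation fits as exponential", {
  u_c <- 8
  m0 <- duplicate_model(3, u_c, 0)
  dat <- simulate_counts(m0, 400, n_bins = 60, seed = 99)
  fit <- fit_mle(dat, z_grid = 3, n_starts = 6, seed = 2)
  expect_lt(unname(fit$mle["u_r"] / fit$mle["u_c"]), 0.05)
  # implied survival is exponential with rate ~ 2 u_c
  expect_equal(unname(fit$mle["u_c"]), u_c, tolerance = 0.1)
})

test_that("profile intervals bracket the MLE with a deficit of 2", {
  truth <- list(z = 3, u_c = 20.07, u_r = 3.26, beta0 = 680.84)
  m <- duplicate_model(truth$z, truth$u_c, truth$u_r)
  dat <- simulate_counts(m, truth$beta0, n_bins = 100, seed = 505)
  fit <- fit_mle(dat, z_grid = 3, n_starts = 6, seed = 1)

  for (p in c("u_c", "beta0")) {
    iv <- profile_interval(dat, 3, p, fit = fit)
    expect_lt(iv$lower, iv$mle)
    expect_gt(iv$upper, iv$mle)
    expect_false(any(iv$at_bound))
    # independent check of the endpoint deficit via a fresh inner optimizer
    fn <- subfunr:::nll_factory(3, dat)
    idx <- match(p, c("u_r", "u_c", "beta0"))
    free <- setdiff(1:3, idx)
    pll <- function(theta) {
      obj <- function(q) {
        par <- numeric(3); par[idx] <- log(theta); par[free] <- q
        fn(par)
      }
      -stats::optim(log(unname(fit$mle[free])), obj,
                    method = "Nelder-Mead",
                    control = list(maxit = 800, reltol = 1e-13))$value
    }
    expect_equal(fit$logLik - pll(iv$lower), 2, tolerance = 1e-4)
    expect_equal(fit$logLik - pll(iv$upper), 2, tolerance = 1e-4)
  }

  # more data, tighter intervals (30 -> 100 bins, same truth and seed)
  dat30 <- simulate_counts(m, truth$beta0, n_bins = 30, seed = 505)
  f30 <- fit_mle(dat30, z_grid = 3, n_starts = 6, seed = 1)
  iv30 <- profile_interval(dat30, 3, "u_c", fit = f30)
  iv100 <- profile_interval(dat, 3, "u_c", fit = fit)
  expect_lt(iv100$upper - iv100$lower, iv30$upper - iv30$lower)
})

test_that("mixture fit over a truncated-Poisson z prior runs end to end", {
  m <- duplicate_model(3, 15, 2.5)
  dat <- simulate_counts(m, 300, n_bins = 40, seed = 7)
  res <- fit_with_z_prior(dat, z_min = 2, z_max = 8, n_starts = 4, seed = 5)
  expect_true(is.finite(res$logLik))
  expect_gt(res$alpha, 0)
  expect_equal(sum(res$prior$weights), 1, tolerance = 1e-12)
  expect_match(res$note, "truncation")
})

test_that("AIC table orders baselines consistently", {
  m <- duplicate_model(3, 15, 2.5)
  dat <- simulate_counts(m, 350, n_bins = 60, seed = 23)
  fit <- fit_mle(dat, z_grid = 2:4, n_starts = 4, seed = 2)
  cmp <- aic_compare(dat, fit, seed = 2)
  expect_setequal(cmp$n_par, c(4, 3, 3, 2))
  ll <- stats::setNames(cmp$logLik, cmp$model)
  # Weibull nests the exponential at shape 1
  expect_gte(ll[["weibull"]], ll[["exponential"]])
  expect_equal(min(cmp$delta_AIC), 0)
  expect_equal(max(cmp$rel_likelihood), 1)
  # the two mechanistic rows differ only in the parameter count
  expect_equal(cmp$logLik[1], cmp$logLik[2])
  expect_equal(cmp$AIC[1] - cmp$AIC[2], 2)
})
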