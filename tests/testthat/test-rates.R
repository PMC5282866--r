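test_that("hazard rate has the right boundary values and long-run limit", {
  u_c <- 1.3; u_r <- 0.4; z <- 5
  m <- duplicate_model(z, u_c, u_r)
  expect_equal(hazard(m, 0), 2 * u_c, tolerance = 1e-12)
  expect_equal(hazard(m, 0, start = z - 1), u_c + 2 * u_r, tolerance = 1e-12)

  # dominant-eigenvalue limit: the smallest |diagonal| of Q*
  lim <- min(abs(diag(build_generator(m)$Qstar)))
  expect_equal(hazard(m, 50 / u_c), lim, tolerance = 1e-6)

  # u_r = 0: the hazard from state 0 is flat at 2 u_c
  m0 <- duplicate_model(3, 2.2, 0)
  expect_equal(hazard(m0, c(0, 0.5, 2, 5)), rep(2 * 2.2, 4),
               tolerance = 1e-10)

  expect_error(hazard(m, -1), ">= 0")
})

test_that("cause-specific hazards decompose the total hazard", {
  m <- duplicate_model(2, 1, 1)
  expect_equal(cause_specific_hazard(m, 0, target = "P"), 2, tolerance = 1e-12)
  expect_equal(cause_specific_hazard(m, 0, target = "S"), 0, tolerance = 1e-12)

  # 2x2 closed form at t = 0.1: lambda_S = x2 / (x1 + x2)
  x <- expm2_row0(-6, 4, -3, 0.1)
  expect_equal(cause_specific_hazard(m, 0.1, target = "S"),
               x[2] / sum(x), tolerance = 1e-10)

  set.seed(5)
  for (i in 1:6) {
    mi <- rand_model()
    ts <- runif(3, 0, 2)
    expect_equal(cause_specific_hazard(mi, ts, target = "S") +
                   cause_specific_hazard(mi, ts, target = "P"),
                 hazard(mi, ts), tolerance = 1e-10)
  }
})

test_that("pseudogenization-time distribution behaves as a defective CDF", {
  m <- duplicate_model(3, 1.1, 0.8)
  expect_equal(pseudo_cdf(m, 0), 0, tolerance = 1e-14)

  p_P <- unname(absorption_probabilities(m)["p_P"])
  expect_equal(pseudo_cdf(m, 100 / m$u_c), p_P, tolerance = 1e-8)

  ts <- seq(0, 4, length.out = 40)
  Ft <- pseudo_cdf(m, ts)
  expect_true(all(diff(Ft) >= 0))
  expect_true(all(Ft <= p_P + 1e-12))
  expect_equal(pseudo_survival(m, ts), 1 - Ft, tolerance = 1e-14)

  # u_r = 0 collapses to exponential survival with rate 2(u_c + u_r)
  u_c <- 4.2
  m0 <- duplicate_model(5, u_c, 0)
  ts <- seq(0, 5 / u_c, length.out = 25)
  expect_equal(pseudo_survival(m0, ts), exponential_survival(ts, u_c),
               tolerance = 1e-10)
})

test_that("pseudogenization rate: boundary value, 2x2 closed form, decay", {
  m <- duplicate_model(2, 1, 1)
  expect_equal(pseudo_rate(m, 0), 2, tolerance = 1e-12)

  # hand closed form at t = 0.1: numerator e0 exp(Qt) v_P over 1 - F(0.1)
  x <- expm2_row0(-6, 4, -3, 0.1)
  num <- sum(x * c(2, 2))
  Qinv_vP <- c(-7 / 9, -2 / 3)   # solve([[-6,4],[0,-3]], c(2,2)) by hand
  Ft <- sum(x * Qinv_vP) - Qinv_vP[1]
  expect_equal(pseudo_rate(m, 0.1), num / (1 - Ft), tolerance = 1e-10)
  expect_equal(pseudo_rate(m, 0.1), 1.963579, tolerance = 1e-6)

  # vanishes at long times whenever subfunctionalization is possible
  expect_lt(pseudo_rate(duplicate_model(4, 1, 0.3), 60), 1e-6)

  # u_r = 0: no subfunctionalization, h_P is the (flat) hazard
  m0 <- duplicate_model(3, 1.7, 0)
  ts <- c(0, 0.4, 1.9)
  expect_equal(pseudo_rate(m0, ts), hazard(m0, ts), tolerance = 1e-10)
})

test_that("h_P equals the cause-specific route through the risk sets", {
  # h_P(t) = lambda_{0P}(t) * P(T > t) / P(T_P > t)
  set.seed(13)
  for (i in 1:6) {
    m <- rand_model()
    b <- build_generator(m)
    for (t in runif(2, 0, 2)) {
      pT <- sum(transient_distribution(b, t))
      lhs <- pseudo_rate(b, t)
      rhs <- cause_specific_hazard(b, t, target = "P") * pT /
        pseudo_survival(b, t)
      expect_equal(lhs, rhs, tolerance = 1e-10)
    }
  }
})

test_that("averaged pseudogenization rate mixes linearly over z", {
  u_c <- 1.2; u_r <- 0.2
  pr <- z_prior(z = 4)
  t <- c(0.1, 1, 3)
  expect_equal(avg_pseudo_rate(pr, u_c, u_r, t),
               pseudo_rate(duplicate_model(4, u_c, u_r), t))

  two <- structure(list(kind = "table", support = c(3L, 6L),
                        weights = c(0.5, 0.5)), class = "z_prior")
  expect_equal(avg_pseudo_rate(two, u_c, u_r, t),
               0.5 * (pseudo_rate(duplicate_model(3, u_c, u_r), t) +
                      pseudo_rate(duplicate_model(6, u_c, u_r), t)),
               tolerance = 1e-12)

  # long-time decay of the mixture
  pois <- z_prior(alpha = 3)
  expect_lt(avg_pseudo_rate(pois, 1, 0.3, 80), 1e-6)

  empty <- structure(list(kind = "table", support = integer(0),
                          weights = numeric(0)), class = "z_prior")
  expect_error(avg_pseudo_rate(empty, 1, 0.3, 1), "empty")
})

test_that("piecewise approximation reproduces the plateau structure", {
  u_c <- 1.4; u_r <- 0.25; z <- 6
  m <- duplicate_model(z, u_c, u_r)
  soj <- 1 / abs(diag(build_generator(m)$Qstar))
  tk <- cumsum(soj)
  expect_equal(piecewise_hazard_approx(m, 0), 2 * u_c)
  expect_equal(piecewise_hazard_approx(m, tk[1] / 2), 2 * u_c)
  expect_equal(piecewise_hazard_approx(m, (tk[1] + tk[z - 1]) / 2), u_c)
  expect_equal(piecewise_hazard_approx(m, tk[z - 1] + 1), u_c + u_r)
  # the uncorrected historical form drops to zero beyond t_z
  expect_equal(piecewise_hazard_approx(m, tk[z] + 0.1, corrected = FALSE), 0)
  expect_equal(piecewise_hazard_approx(m, tk[z] + 0.1, corrected = TRUE),
               u_c + u_r)
})

test_that("rate curves tabulate and export as TSV", {
  m <- duplicate_model(3, 1, 0.2)
  ts <- seq(0.1, 2, length.out = 12)
  cu <- rate_curve(m, ts, which = "pseudo_rate")
  expect_s3_class(cu, "rate_curve")
  expect_equal(cu$rate, pseudo_rate(m, ts))
  expect_error(rate_curve(m, c(1, 1, 2)), "increasing")

  path <- tempfile(fileext = ".tsv")
  write_rate_curve(cu, path)
  back <- utils::read.delim(path, comment.char = "#")
  expect_equal(back$rate, cu$rate, tolerance = 1e-10)
  expect_equal(back$time, cu$time, tolerance = 1e-10)
})
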