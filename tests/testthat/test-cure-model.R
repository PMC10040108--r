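test_that("cure fraction follows the logistic link in standardized age", {
  expect_equal(cure_fraction(BREAST, 0), 0.7, tolerance = 1e-12)
  # x = 1 (age 75): 1 / (1 + exp(-(log(7/3) - 0.15)))
  expect_equal(cure_fraction(BREAST, 1), 1 / (1 + exp(-(log(7 / 3) - 0.15))),
               tolerance = 1e-12)
  expect_equal(round(cure_fraction(BREAST, 1), 4), 0.6676)
  flat <- cure_params(pi60 = 0.4, beta = 0, lambda = 0.2, gamma = 1)
  expect_equal(cure_fraction(flat, c(-1, 0, 2)), rep(0.4, 3))
})

test_that("identity link is validated, not clamped", {
  ident <- cure_params(pi60 = 0.7, beta = -0.2, lambda = 0.1, gamma = 1,
                       link = "identity")
  expect_equal(cure_fraction(ident, 1), 0.5)
  expect_error(cure_fraction(ident, 4), "outside \\[0, 1\\] at x = 4")
  nc <- cure_params(alpha = 1.3, lambda = 0.5, gamma = 0.9,
                    variant = "corrected_no_cure")
  expect_equal(cure_fraction(nc, c(-1, 0, 1)), c(0, 0, 0))
})

test_that("uncured survival and density match scalar arithmetic", {
  expect_equal(uncured_survival(BREAST, 0), 1)
  expect_equal(uncured_survival(BREAST, 5), exp(-0.1 * 5^1.1), tolerance = 1e-12)
  expect_equal(round(uncured_survival(BREAST, 5), 4), 0.5558)
  # the value quoted as "23%" for lambda 0.4, gamma 0.8
  p23 <- cure_params(pi60 = 0.5, lambda = 0.4, gamma = 0.8)
  expect_lt(abs(uncured_survival(p23, 5) - 0.23), 0.005)
  s <- uncured_survival(BREAST, seq(0, 40, by = 0.25))
  expect_true(all(diff(s) < 0))
  expect_equal(uncured_density(BREAST, 5),
               1.1 * 0.1 * 5^0.1 * exp(-0.1 * 5^1.1), tolerance = 1e-12)
  expect_equal(round(uncured_density(BREAST, 5), 4), 0.0718)
  expect_error(uncured_survival(BREAST, -0.1), "t must be")
})

test_that("uncured density integrates to one and matches the hazard identity", {
  for (p in list(BREAST, LUNG)) for (x in c(0, 0.5)) {
    int <- stats::integrate(function(t) uncured_density(p, t, x), 0, 200,
                            rel.tol = 1e-9)
    expect_equal(int$value, 1, tolerance = 1e-4)
    t <- c(0.3, 2, 7)
    expect_equal(uncured_density(p, t, x) / uncured_survival(p, t, x),
                 p$gamma * p$lambda * t^(p$gamma - 1) * exp(-p$delta * x),
                 tolerance = 1e-12)
  }
})

test_that("net survival mixes the cured plateau with uncured survival", {
  expect_equal(net_survival(BREAST, 0), 1)
  expect_equal(net_survival(BREAST, 5), 0.7 + 0.3 * exp(-0.1 * 5^1.1),
               tolerance = 1e-12)
  expect_equal(round(net_survival(BREAST, 5), 4), 0.8667)
  expect_equal(net_survival(BREAST, 1e6), cure_fraction(BREAST, 0),
               tolerance = 1e-12)
})

test_that("excess hazard equals the mixture formula and -d/dt log RS", {
  fu5 <- 1.1 * 0.1 * 5^0.1 * exp(-0.1 * 5^1.1)
  expect_equal(excess_hazard(BREAST, 5),
               0.3 * fu5 / (0.7 + 0.3 * exp(-0.1 * 5^1.1)), tolerance = 1e-12)
  expect_equal(round(excess_hazard(BREAST, 5), 5), 0.02486)
  # pi = 0 degenerates to the plain Weibull hazard
  nc <- cure_params(alpha = 1, lambda = 0.3, gamma = 0.9, delta = -0.2,
                    variant = "corrected_no_cure")
  t <- c(0.5, 2, 9); x <- 0.4
  expect_equal(excess_hazard(nc, t, x),
               0.9 * 0.3 * t^(0.9 - 1) * exp(0.2 * x), tolerance = 1e-12)
  # finite-difference oracle on a grid
  h <- 1e-6
  for (tt in c(0.5, 3, 8, 14)) {
    fd <- -(log(net_survival(BREAST, tt + h)) -
            log(net_survival(BREAST, tt - h))) / (2 * h)
    expect_equal(fd, excess_hazard(BREAST, tt), tolerance = 1e-6)
  }
  expect_error(excess_hazard(BREAST, 0), "t must be > 0")
})

test_that("observed survival is net survival times powered population survival", {
  expect_equal(observed_survival(BREAST, POP, 0, 60), 1)
  p1 <- cure_params(alpha = 1, pi60 = 0.7, beta = -0.15, lambda = 0.1,
                    gamma = 1.1)
  t <- c(1, 5, 12)
  expect_equal(observed_survival(p1, POP, t, 63),
               net_survival(p1, t, std_age(63)) * expected_survival(POP, 63, t),
               tolerance = 1e-12)
  # component-wise oracle at alpha = 1.2
  expect_equal(observed_survival(BREAST, POP, 5, 60),
               (0.7 + 0.3 * exp(-0.1 * 5^1.1)) *
                 exp(-((65 / 88)^11 - (60 / 88)^11))^1.2, tolerance = 1e-12)
  expect_equal(round(observed_survival(BREAST, POP, 5, 60), 4), 0.8453)
})

test_that("exponentiated-Weibull survival generalizes the Weibull", {
  expect_equal(exp_weibull_survival(0, 0.4, 0.8, 4), 1)
  # theta = 1 collapses to the Weibull uncured survival on a (t, x) grid
  grid <- expand.grid(t = c(0, 0.5, 3, 10), x = c(-1, 0, 0.8))
  expect_equal(exp_weibull_survival(grid$t, 0.9, 0.8, 1, delta = -0.3, x = grid$x),
               uncured_survival(LUNG, grid$t, grid$x), tolerance = 1e-12)
  # the 23% / 66% five-year survivals
  expect_equal(round(100 * exp_weibull_survival(5, 0.4, 0.8, 1)), 23)
  expect_equal(round(100 * exp_weibull_survival(5, 0.4, 0.8, 4)), 66)
  expect_error(exp_weibull_survival(5, 0.4, 0.8, 0), "theta must be")
})

test_that("prediction summaries tabulate pi and net survival by age", {
  out <- predict_summary(BREAST, ages = c(40, 60, 70))
  expect_equal(out$pi[out$age == 60], 0.7, tolerance = 1e-12)
  expect_equal(round(out$ns_5y[out$age == 60], 3), 0.867)
  # net survival non-increasing across horizons, all within [0, 1]
  ns <- as.matrix(out[, grep("^ns_", names(out))])
  expect_true(all(ns >= 0 & ns <= 1))
  expect_true(all(apply(ns, 1, function(r) all(diff(r) <= 0))))
  expect_true(all(predict_summary(BREAST, horizons = 0)$ns_0y == 1))
  flat <- cure_params(pi60 = 0.5, beta = 0, lambda = 0.2, gamma = 1, delta = 0)
  out2 <- predict_summary(flat, ages = c(45, 60, 72))
  expect_equal(out2$ns_5y, rep(out2$ns_5y[1], 3))
})

test_that("survival orderings hold across random parameter draws", {
  set.seed(99)
  for (i in 1:25) {
    p <- cure_params(alpha = runif(1, 0.5, 2.5), pi60 = runif(1, 0.05, 0.9),
                     beta = runif(1, -1, 1), lambda = runif(1, 0.05, 1),
                     gamma = runif(1, 0.5, 1.5), delta = runif(1, -0.5, 0.5))
    t <- sort(runif(6, 0, 15)); x <- runif(1, -4 / 3, 1); age <- 60 + 15 * x
    rs <- net_survival(p, t, x)
    so <- observed_survival(p, POP, t, age, x)
    expect_true(all(so <= rs + 1e-12))
    expect_true(all(rs <= 1))
    expect_true(all(diff(rs) <= 0))
    expect_true(all(rs - cure_fraction(p, x) > 0))
  }
})
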