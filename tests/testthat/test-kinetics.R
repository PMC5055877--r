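test_that("logistic curve starts at X0, saturates at Xm, and is monotone", {
  p <- fx$kinetics$saureus
  expect_equal(logistic_X(0, p), p$X0)
  expect_equal(logistic_X(50 / p$mu_max, p), p$Xm, tolerance = 1e-10)
  x <- logistic_X(seq(0, 15, by = 0.1), p)
  expect_true(all(diff(x) >= 0))
  expect_true(all(x <= p$Xm + 1e-12))
})

test_that("logistic closed form matches adaptive integration of the rate law", {
  p <- fx$kinetics$saureus
  sol <- ode_oracle(p, times = c(0, 2, 5, 8, 11))
  expect_equal(logistic_X(sol$time, p), sol$X, tolerance = 1e-6)
  expect_equal(logistic_X(11, p), 0.2232, tolerance = 1e-4)
})

test_that("substrate closed form matches the consumption ODE and decreases", {
  p <- fx$kinetics$saureus
  expect_equal(limlp_S(0, p), p$S0)
  # no consumption terms: substrate stays at S0
  p0 <- kinetic_params(p$mu_max, p$X0, p$Xm, gamma = 0, eta = 0, S0 = 20)
  expect_equal(limlp_S(c(0, 3, 9), p0), rep(20, 3))

  sol <- ode_oracle(p, times = c(0, 2, 5, 11))
  expect_equal(limlp_S(sol$time, p), sol$S, tolerance = 1e-6)
  expect_true(all(diff(limlp_S(0:12, p)) < 0))

  exhausted <- kinetic_params(p$mu_max, p$X0, p$Xm, gamma = 0, eta = 50,
                              S0 = 1)
  expect_warning(limlp_S(12, exhausted), "exhaust")
})

test_that("product closed form matches the formation ODE and the fixtures", {
  p <- fx$kinetics$xcampestris
  expect_equal(lilp_P(0, p), p$P0)
  p0 <- kinetic_params(p$mu_max, p$X0, p$Xm, alpha = 0, beta = 0, P0 = 0)
  expect_equal(lilp_P(c(0, 4, 10), p0), rep(0, 3))

  sol <- ode_oracle(p, times = c(0, 2, 5, 11))
  expect_equal(lilp_P(sol$time, p), sol$P, tolerance = 1e-6)

  # the five fixture parameter sets reproduce the maximum zones at day 11
  fitted_zones <- vapply(fx$kinetics, function(k) lilp_P(11, k), numeric(1))
  expect_equal(unname(fitted_zones), c(30.81, 29.5, 33.08, 29.21, 27.76),
               tolerance = 2e-3)
})

test_that("late product growth approaches the beta * Xm asymptotic slope", {
  p <- fx$kinetics$saureus
  t <- 80
  slope <- (lilp_P(t + 0.5, p) - lilp_P(t - 0.5, p))  # central difference
  expect_equal(slope, p$beta * p$Xm, tolerance = 1e-6)
})

test_that("stationary-phase inversion recovers eta and beta", {
  expect_equal(eta_from_stationary(0, 0.226), 0)
  expect_equal(eta_from_stationary(-0.58, 0.226), 2.566371681,
               tolerance = 1e-9)
  expect_equal(eta_from_stationary(-1, 0.5), 2)
  expect_equal(beta_from_stationary(0, 0.226), 0)
  expect_equal(beta_from_stationary(2, 0.226), 8.8496, tolerance = 1e-4)
  expect_equal(beta_from_stationary(1, 0.226), 4.4248, tolerance = 1e-4)
  expect_error(eta_from_stationary(-0.5, 0), "Xmax")
  expect_error(beta_from_stationary(0.5, -1), "Xmax")
})

test_that("stationary slope is the OLS slope within the window", {
  tc <- time_course(0:12, X = rep(1, 13), S = 30 - 0.5 * (0:12))
  expect_equal(stationary_slope(tc, "S", window = c(5, 11)), -0.5)
  tc2 <- time_course(0:12, X = rep(1, 13), P = rep(4, 13))
  expect_equal(stationary_slope(tc2, "P"), 0)

  # noisy fixture vs the closed-form simple-regression formula
  t <- 0:12
  y <- 2 + 0.8 * t + with_seed_helper(77, rnorm(13, 0, 0.3))
  tc3 <- time_course(t, X = rep(1, 13), P = y)
  w <- t >= 5 & t <= 11
  slope_formula <- sum((t[w] - mean(t[w])) * (y[w] - mean(y[w]))) /
    sum((t[w] - mean(t[w]))^2)
  expect_equal(stationary_slope(tc3, "P"), slope_formula, tolerance = 1e-12)

  expect_error(stationary_slope(tc, "S", window = c(20, 30)), "2 points")
})

test_that("goodness reports R2, RMSE and AAD from their definitions", {
  y <- c(4, 8, 15, 16)
  g <- goodness(y, y)
  expect_equal(unlist(g), c(r2 = 1, rmse = 0, aad_pct = 0))
  g0 <- goodness(y, rep(mean(y), 4))
  expect_equal(g0$r2, 0)

  pred <- y + c(0.5, -0.5, 1, -1)
  g1 <- goodness(y, pred)
  expect_equal(g1$rmse, sqrt(mean((y - pred)^2)))
  expect_equal(g1$aad_pct, 100 * mean(abs(y - pred) / y))
})

test_that("the logarithmic kernel argument never dips below one", {
  for (s in 1:50) {
    p <- random_kinetic_params(seed = 5000 + s)
    t <- seq(0, 15, by = 0.5)
    # ln L >= 0 <=> L >= 1; evaluated through the overflow-safe identity
    lnL <- (p$mu_max * t + log(p$X0 / p$Xm) +
              log1p((p$Xm - p$X0) / p$X0 * exp(-p$mu_max * t)))
    expect_true(all(lnL >= -1e-12))
  }
})

test_that("fixture product formation is predominantly growth-associated", {
  for (k in fx$kinetics) expect_gt(k$alpha, k$beta)
})
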