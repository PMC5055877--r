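test_that("design-response generator is exact at zero noise and seeded", {
  des <- toy_design(3L, 4L)
  m <- random_quadratic_model(3L, seed = 1)
  y0 <- gen_ccd_responses(des, m, noise_sd = 0)
  expect_equal(y0, predict(m, coded_matrix(des)))
  y1 <- gen_ccd_responses(des, m, noise_sd = 0.3, seed = 4)
  y2 <- gen_ccd_responses(des, m, noise_sd = 0.3, seed = 4)
  expect_identical(y1, y2)
  expect_false(identical(y1, gen_ccd_responses(des, m, 0.3, seed = 5)))
  expect_error(gen_ccd_responses(des, random_quadratic_model(4L, 2), 0),
               "factors")
})

test_that("generator noise has the requested spread", {
  x <- with_seed_helper(2, matrix(runif(1000 * 2, -1, 1), ncol = 2))
  m <- random_quadratic_model(2L, seed = 3)
  y <- gen_ccd_responses(x, m, noise_sd = 0.1, seed = 21)
  resid <- y - predict(m, x)
  expect_gt(stats::sd(resid), 0.09)
  expect_lt(stats::sd(resid), 0.11)
})

test_that("time-course generator is exact at zero noise and unbiased with it", {
  p <- fx$kinetics$bsubtilis
  tc <- gen_timecourse(p, times = 0:12)
  expect_equal(tc$X, logistic_X(0:12, p))
  expect_equal(tc$S, limlp_S(0:12, p))
  expect_equal(tc$P, lilp_P(0:12, p))
  expect_equal(tc$X[1L], p$X0)
  expect_equal(tc$S[1L], p$S0)
  expect_equal(tc$P[1L], p$P0)

  # CLT band: mean of 500 noisy replicates stays within 2 SE of the curve
  times <- c(0, 3, 6, 9, 12)
  reps <- vapply(1:500, function(s) {
    gen_timecourse(p, times = times, noise_sd_X = 0.005, seed = s,
                   series = "X")$X
  }, numeric(length(times)))
  se <- 0.005 / sqrt(500)
  dev <- abs(rowMeans(reps) - logistic_X(times, p))
  # clipping at zero biases the t = 0 point upward; allow for it there
  expect_true(all(dev[-1L] <= 2 * se + 1e-12))
})

test_that("reference fixtures carry the documented worked-example values", {
  expect_equal(fx$models$saureus$coefficients[1L], 20.924)
  expect_equal(fx$models$bsubtilis$coefficients[1L], 20.3477)
  expect_equal(fx$kinetics$saureus$mu_max, 0.7431)
  expect_equal(fx$kinetics$xcampestris$alpha, 124.62)
  expect_identical(length(fx$models), 5L)
  expect_identical(nrow(generate_ccfd(fx$factors)), 50L)
  # both temperature variants are present, centered at 30 and 25 degC
  expect_equal(fx$factors$factors[[3]]$center, 30)
  expect_equal(fx$factors_alt$factors[[3]]$center, 25)
  expect_true(all(c("saureus_model", "saureus_kinetics") %in%
                    fx$manifest$fixture))
})

test_that("surface fitting recovers generator coefficients within 3 SE", {
  des <- generate_ccfd(fx$factors, randomize = FALSE)
  truth <- fx$models$saureus
  n_rep <- 200L
  inside <- matrix(FALSE, n_rep, 21L)
  for (r in seq_len(n_rep)) {
    y <- gen_ccd_responses(des, truth, noise_sd = 0.1, seed = 9000 + r)
    fit <- fit_quadratic(des, y)
    se <- sqrt(diag(suppressWarnings(stats::vcov(fit$lm))))
    inside[r, ] <- abs(fit$model$coefficients - truth$coefficients) <= 3 * se
  }
  coverage <- colMeans(inside)  # per coefficient, across replicates
  expect_true(all(coverage >= 0.95))
})

test_that("kinetic refits recover generator parameters within 15 percent", {
  truth <- fx$kinetics$saureus
  pars <- c("mu_max", "X0", "Xm", "gamma", "eta", "alpha", "beta")
  # additive noise at 2% of each series' amplitude (the informative span of
  # the trajectory: growth range, substrate consumed, final zone size)
  sig <- kin_noise_sigmas(truth, frac = 0.02)
  rel_err <- matrix(NA_real_, 50L, length(pars),
                    dimnames = list(NULL, pars))
  for (s in 1:50) {
    tc <- gen_timecourse(truth, times = 0:12, noise_sd_X = sig["X"],
                         noise_sd_S = sig["S"], noise_sd_P = sig["P"],
                         seed = 9500 + s)
    tc$X <- pmax(tc$X, 1e-6)  # biomass assays cannot report <= 0
    # initial substrate and product are set by the protocol, not assayed
    fit <- fit_kinetics(tc, S0 = truth$S0, P0 = truth$P0)
    rel_err[s, ] <- vapply(pars, function(f) {
      abs(fit[[f]] - truth[[f]]) / truth[[f]]
    }, numeric(1))
  }
  med <- apply(rel_err, 2L, stats::median)
  expect_true(all(med < 0.15))
})

test_that("kinetic estimates are near-unbiased under 5% multiplicative noise", {
  truth <- fx$kinetics$saureus
  pars <- c("mu_max", "X0", "Xm", "gamma", "eta", "alpha", "beta")
  est <- vapply(1:50, function(s) {
    tc <- gen_timecourse(truth, times = 0:12, noise_sd_X = 0.05,
                         noise_sd_S = 0.05, noise_sd_P = 0.05,
                         relative = TRUE, seed = 7500 + s)
    tc$X <- pmax(tc$X, 1e-6)
    fit <- fit_kinetics(tc)
    vapply(pars, function(f) fit[[f]], numeric(1))
  }, numeric(length(pars)))
  tr <- vapply(pars, function(f) truth[[f]], numeric(1))
  bias <- abs(rowMeans(est) - tr) / tr
  expect_true(all(bias < 0.15))
})
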