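test_that("noise-free responses recover the generating coefficients", {
  for (n in 2:5) {
    des <- toy_design(n, n_c = 6L)
    truth <- random_quadratic_model(n, seed = 100 + n)
    y <- gen_ccd_responses(des, truth, noise_sd = 0)
    fit <- fit_quadratic(des, y)
    expect_lt(max(abs(fit$model$coefficients - truth$coefficients)), 1e-8)
    expect_equal(fit$summary$r2, 1, tolerance = 1e-10)
  }
})

test_that("constant response degenerates to a flagged intercept-only model", {
  des <- toy_design(3L, 4L)
  expect_warning(fit <- fit_quadratic(des, rep(7, nrow(des))),
                 "zero response variance")
  expect_equal(fit$model$coefficients[1L], 7)
  expect_true(all(fit$model$coefficients[-1L] == 0))
  expect_equal(fit$summary$r2, 0)
})

test_that("fit dimensions are validated", {
  des <- toy_design(3L, 4L)
  expect_error(fit_quadratic(des, rep(1, 5)), "length")
  expect_error(fit_quadratic(des, c(rep(1, nrow(des) - 1), NA)), "missing")
  small <- toy_design(3L, 4L)[1:8, ]  # fewer runs than the 10 terms
  attr(small, "factor_names") <- c("A", "B", "C")
  expect_error(fit_quadratic(small, rnorm(8)), "more runs")
})

test_that("R-squared matches a definition-based residual summation", {
  des <- toy_design(4L, 6L)
  truth <- random_quadratic_model(4L, seed = 11)
  y <- gen_ccd_responses(des, truth, noise_sd = 0.1, seed = 12)
  fit <- fit_quadratic(des, y)
  res <- y - predict(fit$model, coded_matrix(des))
  r2_direct <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(fit$summary$r2, r2_direct, tolerance = 1e-10)
})

test_that("fit metrics reduce correctly in the exact and mean-only cases", {
  y <- c(3, 5, 9, 11, 6)
  m <- fit_metrics(y, y, p_terms = 2L)
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$aad_pct, 0)

  m <- fit_metrics(y, rep(mean(y), 5), p_terms = 1L)
  expect_equal(m$r2, 0)

  expect_warning(m <- fit_metrics(c(0, 1, 2), c(0.1, 1, 2), p_terms = 1L),
                 "AAD")
  expect_true(is.na(m$aad_pct))
})

test_that("PRESS via the hat shortcut equals brute-force leave-one-out", {
  des <- toy_design(3L, 5L)
  truth <- random_quadratic_model(3L, seed = 31)
  y <- gen_ccd_responses(des, truth, noise_sd = 0.4, seed = 32)
  fit <- fit_quadratic(des, y)

  mm <- build_design_matrix(des)
  press_loo <- 0
  for (i in seq_len(nrow(mm))) {
    b <- qr.coef(qr(mm[-i, , drop = FALSE]), y[-i])
    press_loo <- press_loo + (y[i] - drop(mm[i, ] %*% b))^2
  }
  expect_equal(fit$summary$press, press_loo, tolerance = 1e-8)
  expect_equal(fit$summary$pred_r2,
               1 - press_loo / sum((y - mean(y))^2), tolerance = 1e-8)
})

test_that("lack-of-fit partitions the residual into replicate and model error", {
  des <- toy_design(3L, 5L)
  truth <- random_quadratic_model(3L, seed = 41)
  y <- gen_ccd_responses(des, truth, noise_sd = 0.3, seed = 42)
  fit <- fit_quadratic(des, y)
  lof <- lack_of_fit(des, y, fit)
  ss_res <- sum(fit$residuals^2)
  expect_equal(lof$ss_lof + lof$ss_pe, ss_res, tolerance = 1e-8 * ss_res)
  expect_equal(lof$df_lof + lof$df_pe, nrow(des) - 10L)  # n - p_terms
  expect_true(lof$computable)

  # noise-free: the quadratic interpolates every group mean of its own surface
  y0 <- gen_ccd_responses(des, truth, noise_sd = 0)
  fit0 <- fit_quadratic(des, y0)
  lof0 <- lack_of_fit(des, y0, fit0)
  expect_lt(lof0$ss_lof, 1e-16)
  expect_true(is.na(lof0$f) || lof0$f < 1e-6)

  # identical replicates: pure error exactly zero, F flagged undefined
  expect_true(lof0$degenerate)
})

test_that("lack of fit is reported not-computable without replicates", {
  des <- toy_design(2L, 1L)
  x <- coded_matrix(des)
  keep <- !duplicated(apply(x, 1, paste, collapse = ","))
  d2 <- des[keep, ]
  attr(d2, "factor_names") <- attr(des, "factor_names")
  y <- with_seed_helper(5, rnorm(nrow(d2)))
  m <- random_quadratic_model(2L, seed = 51)
  lof <- lack_of_fit(d2, y, m, p_terms = 6L)
  expect_false(lof$computable)
  expect_true(is.na(lof$f))
})

test_that("sequential tiers attribute zero gain beyond the generating order", {
  des <- toy_design(3L, 5L)
  # pure linear truth
  lin <- quadratic_model(2, c(1, -0.5, 0.25), rep(0, 3), rep(0, 3),
                         factor_names = c("A", "B", "C"))
  y <- gen_ccd_responses(des, lin, noise_sd = 0)
  seq_ss <- sequential_model_ss(des, y)
  expect_lt(seq_ss$ss[seq_ss$tier == "2FI"], 1e-10)
  expect_lt(seq_ss$ss[seq_ss$tier == "quadratic"], 1e-10)

  # intercept-only truth
  y0 <- rep(3, nrow(des)) + with_seed_helper(6, rnorm(nrow(des), 0, 1e-12))
  s0 <- sequential_model_ss(des, y0)
  expect_true(all(s0$ss[-1L] < 1e-10))
})

test_that("quadratic-vs-2FI F ratio matches two independent OLS fits", {
  des <- toy_design(4L, 6L)
  truth <- random_quadratic_model(4L, seed = 61)
  y <- gen_ccd_responses(des, truth, noise_sd = 0.2, seed = 62)
  seq_ss <- sequential_model_ss(des, y)

  mm <- build_design_matrix(des)
  cols_2fi <- 1:11           # intercept, 4 linear, 6 interactions
  cols_quad <- 1:15
  rss <- function(cols) sum(qr.resid(qr(mm[, cols, drop = FALSE]), y)^2)
  d_ss <- rss(cols_2fi) - rss(cols_quad)
  df_res <- nrow(des) - 15L
  f_direct <- (d_ss / 4) / (rss(cols_quad) / df_res)
  row <- seq_ss[seq_ss$tier == "quadratic", ]
  expect_equal(row$ss, d_ss, tolerance = 1e-8)
  expect_equal(row$f, f_direct, tolerance = 1e-8)

  # pure-cubic columns are aliased with the linear ones on a 3-level design
  expect_true(any(grepl("\\^3", attr(seq_ss, "aliased"))))
})
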