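# Parameter estimation for the logistic / Luedeking-Piret family.
#
# Estimation is sequential, mirroring the model structure: the logistic
# growth parameters are fitted first from the biomass series (bounded
# nonlinear least squares, deterministic multi-start), then the product and
# substrate coefficient pairs are estimated conditional on the growth fit.
# Conditional on (mu_max, X0, Xm), the product and substrate closed forms
# are LINEAR in (alpha, beta) and (gamma, eta):
#   P(t) - P0 =  alpha * f1(t) + beta * f2(t)
#   S0 - S(t) =  gamma * f1(t) + eta  * f2(t)
# with f1 = X(t) - X0 and f2 = (Xm/mu_max) ln L(t), so those steps are
# non-negative linear least squares and need no iteration or starting values.

# plain R-squared, without the AAD bookkeeping of fit_metrics() (a product
# series legitimately starts at 0 mm, where AAD is undefined)
r_squared <- function(observed, predicted) {
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(0)
  1 - sum((observed - predicted)^2) / ss_tot
}

# shared regressor pair for the Luedeking-Piret integrals
lp_basis <- function(t, growth) {
  cbind(f1 = logistic_X(t, growth) - growth$X0,
        f2 = (growth$Xm / growth$mu_max) *
          log_kernel(t, growth$mu_max, growth$X0, growth$Xm))
}

as_growth_params <- function(growth) {
  if (inherits(growth, "kinetic_params")) return(growth)
  if (is.list(growth) && all(c("mu_max", "X0", "Xm") %in% names(growth))) {
    return(kinetic_params(growth$mu_max, growth$X0, growth$Xm))
  }
  stop("'growth' must supply mu_max, X0 and Xm", call. = FALSE)
}

#' Fit the logistic growth model to a biomass series
#'
#' Bounded nonlinear least squares on the closed-form logistic curve.
#' Starting values are taken from the data (first observation for `X0`,
#' series maximum for `Xm`, log-linear slope over the first half of the
#' points for `mu_max`) and perturbed over a small deterministic multi-start
#' grid; the best converged fit is returned.
#'
#' @param tc A [time_course()] (or data.frame with `time` and `X`).
#' @param n_starts Number of multi-start attempts.
#' @param seed Seed for the start perturbations (deterministic by default).
#' @return List with `mu_max`, `X0`, `Xm`, `r2`, `fitted`, and the underlying
#'   `nls` object as `fit`.
#' @export
fit_logistic <- function(tc, n_starts = 5L, seed = 71L) {
  stopifnot(inherits(tc, "data.frame"), !is.null(tc$time), !is.null(tc$X))
  t <- tc$time
  X <- tc$X
  if (length(X) < 4L) stop("need at least 4 biomass points", call. = FALSE)
  if (any(X <= 0)) stop("biomass must be positive", call. = FALSE)
  if (diff(range(X)) < 1e-10 * max(X)) {
    stop("biomass series is constant: logistic parameters are not ",
         "identifiable", call. = FALSE)
  }

  x0_init <- max(X[1L], 1e-8)
  xm_init <- max(X)
  half <- seq_len(max(2L, floor(length(X) / 2)))
  mu_init <- unname(stats::coef(stats::lm(log(X[half]) ~ t[half]))[2L])
  if (!is.finite(mu_init) || mu_init <= 0) mu_init <- 0.5

  scales <- with_seed(seed, {
    more <- matrix(stats::runif(3L * max(n_starts - 1L, 0L), 0.4, 2.5),
                   ncol = 3L)
    unname(rbind(c(1, 1, 1), more))  # first start: the data-driven guesses
  })

  best <- NULL
  diags <- character(0)
  for (i in seq_len(min(n_starts, nrow(scales)))) {
    st <- list(mu = mu_init * scales[i, 1L],
               X0 = x0_init * scales[i, 2L],
               Xm = xm_init * scales[i, 3L])
    if (st$X0 >= st$Xm) st$X0 <- st$Xm / 10
    fit <- tryCatch(
      minpack.lm::nlsLM(
        X ~ Xm / (1 + (Xm - X0) / X0 * exp(-mu * t)),
        start = st,
        lower = c(mu = 1e-6, X0 = 1e-10, Xm = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 500L,
                                             ftol = 1e-15, ptol = 1e-15)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diags <- c(diags, conditionMessage(fit))
      next
    }
    ss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) {
    stop("logistic fit failed to converge from any start; messages: ",
         paste(unique(diags), collapse = "; "), call. = FALSE)
  }
  co <- stats::coef(best$fit)
  if (co[["X0"]] >= co[["Xm"]]) {
    stop("logistic fit converged to X0 >= Xm: data show no saturating growth",
         call. = FALSE)
  }
  pred <- stats::fitted(best$fit)
  list(mu_max = unname(co[["mu"]]), X0 = unname(co[["X0"]]),
       Xm = unname(co[["Xm"]]), r2 = r_squared(X, pred),
       fitted = as.numeric(pred), fit = best$fit)
}

#' Fit the Luedeking-Piret product coefficients
#'
#' Estimates `(alpha, beta)` of the product closed form conditional on fitted
#' logistic growth parameters, with `P0` fixed at the first product
#' observation. The problem is linear in the coefficients, so it is solved by
#' non-negative linear least squares.
#'
#' @param tc A [time_course()] with a `P` series.
#' @param growth Growth parameters: a [kinetic_params()] or the list returned
#'   by [fit_logistic()].
#' @param P0 Initial product level to anchor the curve at. `NULL` (default)
#'   uses the first product observation; supply the known value when the
#'   initial condition is set by the protocol (no inhibition zone exists at
#'   inoculation) rather than measured.
#' @return List with `alpha`, `beta`, `P0`, `r2`, `fitted`.
#' @export
fit_lilp <- function(tc, growth, P0 = NULL) {
  stopifnot(inherits(tc, "data.frame"), !is.null(tc$time))
  if (is.null(tc$P)) stop("time course has no product series", call. = FALSE)
  growth <- as_growth_params(growth)
  if (is.null(P0)) P0 <- tc$P[1L]
  B <- lp_basis(tc$time, growth)
  sol <- pracma::lsqnonneg(B, tc$P - P0)
  pred <- P0 + drop(B %*% sol$x)
  list(alpha = sol$x[1L], beta = sol$x[2L], P0 = P0,
       r2 = r_squared(tc$P, pred), fitted = pred)
}

#' Fit the modified Luedeking-Piret substrate coefficients
#'
#' Estimates `(gamma, eta)` of the substrate closed form conditional on
#' fitted logistic growth parameters, with `S0` fixed at the first substrate
#' observation; solved by non-negative linear least squares.
#'
#' @param tc A [time_course()] with an `S` series.
#' @param growth Growth parameters, as in [fit_lilp()].
#' @param S0 Initial substrate to anchor the curve at. `NULL` (default) uses
#'   the first substrate observation; supply the formulated medium
#'   concentration when it is known (e.g. 20 g/L for a 2 % w/v sucrose
#'   medium), since a single noisy t = 0 assay propagates into both
#'   coefficients.
#' @return List with `gamma`, `eta`, `S0`, `r2`, `fitted`.
#' @export
fit_limlp <- function(tc, growth, S0 = NULL) {
  stopifnot(inherits(tc, "data.frame"), !is.null(tc$time))
  if (is.null(tc$S)) stop("time course has no substrate series", call. = FALSE)
  growth <- as_growth_params(growth)
  if (is.null(S0)) S0 <- tc$S[1L]
  B <- lp_basis(tc$time, growth)
  sol <- pracma::lsqnonneg(B, S0 - tc$S)
  pred <- S0 - drop(B %*% sol$x)
  list(gamma = sol$x[1L], eta = sol$x[2L], S0 = S0,
       r2 = r_squared(tc$S, pred), fitted = pred)
}

#' Fit the full kinetic model to a batch time-course
#'
#' Convenience wrapper: fits the logistic growth model to the biomass series,
#' then the product and/or substrate coefficient pairs conditional on it.
#'
#' @param tc A [time_course()].
#' @param window Stationary-phase window (days), recorded for reporting.
#' @param S0,P0 Known initial substrate / product values, passed through to
#'   [fit_limlp()] / [fit_lilp()]; `NULL` anchors on the first observations.
#' @return A [kinetic_params()] carrying all fitted values, with per-model
#'   R-squared in attribute `r2`.
#' @export
fit_kinetics <- function(tc, window = c(5, 11), S0 = NULL, P0 = NULL) {
  g <- fit_logistic(tc)
  r2 <- c(logistic = g$r2)
  alpha <- beta <- gamma <- eta <- 0
  S0_out <- 20
  P0_out <- 0
  if (!is.null(tc$P)) {
    fp <- fit_lilp(tc, g, P0 = P0)
    alpha <- fp$alpha
    beta <- fp$beta
    P0_out <- max(fp$P0, 0)  # a noisy first observation may dip below zero
    r2 <- c(r2, lilp = fp$r2)
  }
  if (!is.null(tc$S)) {
    fs <- fit_limlp(tc, g, S0 = S0)
    gamma <- fs$gamma
    eta <- fs$eta
    S0_out <- fs$S0
    r2 <- c(r2, limlp = fs$r2)
  }
  out <- kinetic_params(g$mu_max, g$X0, g$Xm, gamma = gamma, eta = eta,
                        alpha = alpha, beta = beta, S0 = S0_out, P0 = P0_out)
  attr(out, "r2") <- r2
  attr(out, "window") <- window
  out
}
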