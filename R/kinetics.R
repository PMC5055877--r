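# Unstructured batch-fermentation kinetics.
#
# Biomass follows logistic growth,
#   dX/dt = mu_max X (1 - X/Xm),
# whose solution is the sigmoid X(t) = X0 e^{mu t} / (1 - (X0/Xm)(1 - e^{mu t})).
# Product formation follows the Luedeking-Piret rate law
#   dP/dt = alpha dX/dt + beta X,
# and substrate consumption its modified form
#   -dS/dt = gamma dX/dt + eta X.
# Substituting the logistic solution gives the closed forms implemented here;
# both integrals use the same logarithmic kernel
#   ln L(t), L(t) = 1 + (X0/Xm)(e^{mu t} - 1)  >= 1 for t >= 0,
# since (Xm/mu) ln L(t) is the running integral of X.

#' Kinetic parameters for logistic growth with Luedeking-Piret kinetics
#'
#' @param mu_max Maximum specific growth rate (1/day), > 0.
#' @param X0 Initial biomass (g/L), 0 < X0 < Xm.
#' @param Xm Maximum (carrying-capacity) biomass (g/L).
#' @param gamma Growth-associated substrate coefficient (g substrate per g
#'   biomass), >= 0.
#' @param eta Non-growth-associated substrate coefficient
#'   (g substrate per g biomass per day), >= 0.
#' @param alpha Growth-associated product coefficient (mm inhibition zone per
#'   g biomass), >= 0.
#' @param beta Non-growth-associated product coefficient (mm per g biomass
#'   per day), >= 0.
#' @param S0 Initial substrate (g/L); defaults to 20 g/L (2 % w/v sucrose).
#' @param P0 Initial product proxy (mm inhibition zone); defaults to 0 (no
#'   zone at inoculation).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(mu_max, X0, Xm, gamma = 0, eta = 0,
                           alpha = 0, beta = 0, S0 = 20, P0 = 0) {
  p <- list(mu_max = mu_max, X0 = X0, Xm = Xm, gamma = gamma, eta = eta,
            alpha = alpha, beta = beta, S0 = S0, P0 = P0)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1)))) {
    stop("all kinetic parameters must be finite numeric scalars", call. = FALSE)
  }
  if (p$mu_max <= 0) stop("mu_max must be > 0", call. = FALSE)
  if (!(p$X0 > 0 && p$X0 < p$Xm)) {
    stop("need 0 < X0 < Xm", call. = FALSE)
  }
  for (f in c("gamma", "eta", "alpha", "beta", "S0", "P0")) {
    if (p[[f]] < 0) stop(sprintf("%s must be >= 0", f), call. = FALSE)
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  growth:    mu_max = %g /day, X0 = %g g/L, Xm = %g g/L\n",
              x$mu_max, x$X0, x$Xm))
  cat(sprintf("  substrate: gamma = %g, eta = %g, S0 = %g g/L\n",
              x$gamma, x$eta, x$S0))
  cat(sprintf("  product:   alpha = %g, beta = %g, P0 = %g mm\n",
              x$alpha, x$beta, x$P0))
  invisible(x)
}

# log of the logistic kernel L(t) = 1 + (X0/Xm)(exp(mu t) - 1), written in a
# form that cannot overflow for large mu*t:
#   ln L = mu t + ln(X0/Xm) + log1p((Xm - X0)/(X0 e^{mu t}))
log_kernel <- function(t, mu, X0, Xm) {
  mu * t + log(X0 / Xm) + log1p((Xm - X0) / X0 * exp(-mu * t))
}

#' Logistic biomass curve
#'
#' Closed-form solution of `dX/dt = mu_max X (1 - X/Xm)`: starts at `X0`,
#' increases monotonically and saturates at `Xm`. Evaluated in the
#' overflow-safe form `Xm / (1 + ((Xm - X0)/X0) exp(-mu_max t))`.
#'
#' @param t Time in days (vectorized).
#' @param p A [kinetic_params()].
#' @return Biomass (g/L) at each `t`.
#' @export
logistic_X <- function(t, p) {
  stopifnot(inherits(p, "kinetic_params"))
  p$Xm / (1 + (p$Xm - p$X0) / p$X0 * exp(-p$mu_max * t))
}

#' Substrate curve of the logistic-incorporated modified Luedeking-Piret model
#'
#' Integral of `-dS/dt = gamma dX/dt + eta X` along the logistic biomass
#' curve:
#' `S(t) = S0 - gamma (X(t) - X0) - (eta Xm / mu_max) ln L(t)`,
#' with `L(t) = 1 + (X0/Xm)(e^{mu_max t} - 1)`. Both consumption terms are
#' non-negative, so `S` decreases from `S0`. A negative predicted value is
#' returned as-is with a substrate-exhaustion warning (the unstructured model
#' has no substrate limitation built in).
#'
#' @inheritParams logistic_X
#' @return Substrate (g/L) at each `t`.
#' @export
limlp_S <- function(t, p) {
  stopifnot(inherits(p, "kinetic_params"))
  s <- p$S0 - p$gamma * (logistic_X(t, p) - p$X0) -
    (p$eta * p$Xm / p$mu_max) * log_kernel(t, p$mu_max, p$X0, p$Xm)
  if (any(s < 0)) {
    warning("predicted substrate below 0: substrate exhausted before the ",
            "requested time", call. = FALSE)
  }
  s
}

#' Product curve of the logistic-incorporated Luedeking-Piret model
#'
#' Integral of `dP/dt = alpha dX/dt + beta X` along the logistic biomass
#' curve:
#' `P(t) = P0 + alpha (X(t) - X0) + (beta Xm / mu_max) ln L(t)`.
#' Non-decreasing for `alpha, beta >= 0`; for large `mu_max t` the curve
#' grows linearly with asymptotic slope `beta Xm` (the non-growth-associated
#' contribution of a stationary-phase culture at `Xm`).
#'
#' @inheritParams logistic_X
#' @return Product proxy (mm inhibition zone) at each `t`.
#' @export
lilp_P <- function(t, p) {
  stopifnot(inherits(p, "kinetic_params"))
  p$P0 + p$alpha * (logistic_X(t, p) - p$X0) +
    (p$beta * p$Xm / p$mu_max) * log_kernel(t, p$mu_max, p$X0, p$Xm)
}

#' Non-growth-associated coefficients from stationary-phase slopes
#'
#' In stationary phase the culture sits at `X = Xmax` and growth-associated
#' terms vanish, so the rate laws reduce to `-dS/dt = eta Xmax` and
#' `dP/dt = beta Xmax`. Given the observed stationary-phase slope these
#' invert to `eta = -(dS/dt)/Xmax` and `beta = (dP/dt)/Xmax`.
#'
#' @param dSdt_stationary Stationary-phase substrate slope (g/L/day,
#'   typically negative).
#' @param dPdt_stationary Stationary-phase product slope (mm/day).
#' @param Xmax Maximum biomass (g/L), > 0.
#' @return The coefficient (scalar).
#' @examples
#' eta_from_stationary(-0.58, 0.226)
#' beta_from_stationary(2, 0.226)
#' @export
eta_from_stationary <- function(dSdt_stationary, Xmax) {
  if (!is.numeric(Xmax) || Xmax <= 0) stop("Xmax must be > 0", call. = FALSE)
  -dSdt_stationary / Xmax
}

#' @rdname eta_from_stationary
#' @export
beta_from_stationary <- function(dPdt_stationary, Xmax) {
  if (!is.numeric(Xmax) || Xmax <= 0) stop("Xmax must be > 0", call. = FALSE)
  dPdt_stationary / Xmax
}

#' Batch time-course container
#'
#' @param times Sampling times in days, strictly increasing, starting at
#'   t >= 0.
#' @param X Biomass (g/L), same length as `times`.
#' @param S Optional substrate series (g/L).
#' @param P Optional product-proxy series (mm).
#' @return A `data.frame` of class `time_course` with columns `time`, `X`,
#'   and optionally `S`, `P`.
#' @export
time_course <- function(times, X, S = NULL, P = NULL) {
  stopifnot(is.numeric(times), length(times) >= 2L)
  if (times[1L] < 0 || any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing and start at t >= 0",
         call. = FALSE)
  }
  if (length(X) != length(times)) stop("X length mismatch", call. = FALSE)
  out <- data.frame(time = times, X = X)
  if (!is.null(S)) {
    stopifnot(length(S) == length(times))
    out$S <- S
  }
  if (!is.null(P)) {
    stopifnot(length(P) == length(times))
    out$P <- P
  }
  structure(out, class = c("time_course", "data.frame"))
}

#' Stationary-phase slope of a measured series
#'
#' Ordinary least-squares slope of substrate or product versus time,
#' restricted to a time window. The default window (days 5 to 11) covers the
#' stationary phase of the reference fermentation; override it for other
#' organisms.
#'
#' @param tc A [time_course()].
#' @param series `"S"` or `"P"`.
#' @param window Length-2 inclusive time interval in days.
#' @return Slope in series units per day.
#' @export
stationary_slope <- function(tc, series = c("S", "P"), window = c(5, 11)) {
  series <- match.arg(series)
  stopifnot(inherits(tc, "data.frame"), length(window) == 2L)
  if (is.null(tc[[series]])) {
    stop(sprintf("time course has no '%s' series", series), call. = FALSE)
  }
  keep <- tc$time >= window[1L] & tc$time <= window[2L]
  if (sum(keep) < 2L) {
    stop("need at least 2 points inside the stationary window", call. = FALSE)
  }
  unname(stats::coef(stats::lm(tc[[series]][keep] ~ tc$time[keep]))[2L])
}

#' Goodness of fit between observed and model-predicted series
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return List with `r2`, `rmse` and `aad_pct`, defined as in
#'   [fit_metrics()].
#' @export
goodness <- function(observed, predicted) {
  m <- fit_metrics(observed, predicted, p_terms = 0L)
  list(r2 = m$r2, rmse = m$rmse, aad_pct = m$aad_pct)
}
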