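# Seeded synthetic-data generators. These define the statistical structure
# the analysis modules assume: quadratic surface plus i.i.d. homoscedastic
# Gaussian noise for design responses, and closed-form kinetic trajectories
# plus additive (optionally signal-relative) Gaussian noise for time-courses.

#' Simulate responses for a design from a known quadratic surface
#'
#' `response_i = predict(model, coded_i) + e_i`, `e_i ~ N(0, noise_sd^2)`,
#' seeded and reproducible.
#'
#' @param design A `ccfd_design` (or coded matrix).
#' @param model The true [quadratic_model()].
#' @param noise_sd Response-unit noise standard deviation, >= 0.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of simulated responses, one per run.
#' @export
gen_ccd_responses <- function(design, model, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "quadratic_model"), noise_sd >= 0)
  x <- if (inherits(design, "ccfd_design")) coded_matrix(design) else as.matrix(design)
  if (ncol(x) != model$n_factors) {
    stop(sprintf("design has %d factors, model has %d", ncol(x),
                 model$n_factors), call. = FALSE)
  }
  mu <- predict(model, x)
  eps <- if (noise_sd == 0) {
    numeric(nrow(x))
  } else if (is.null(seed)) {
    stats::rnorm(nrow(x), 0, noise_sd)
  } else {
    with_seed(seed, stats::rnorm(nrow(x), 0, noise_sd))
  }
  mu + eps
}

#' Simulate a batch fermentation time-course
#'
#' Biomass, substrate and product series are the closed-form logistic /
#' Luedeking-Piret curves plus seeded Gaussian noise. With
#' `relative = FALSE` (default) the `noise_sd_*` values are absolute series
#' units; with `relative = TRUE` each point's noise standard deviation is
#' `noise_sd_* * |signal|`, a multiplicative error model in which early
#' near-zero biomass is measured proportionally, not with a fixed floor.
#' Biomass is clipped at 0.
#'
#' @param params True [kinetic_params()].
#' @param times Sampling times (days), strictly increasing.
#' @param noise_sd_X,noise_sd_S,noise_sd_P Noise levels per series (absolute
#'   units, or fractions of signal when `relative = TRUE`).
#' @param relative Interpret noise levels as fractions of the local signal?
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param series Which series to include.
#' @return A [time_course()].
#' @export
gen_timecourse <- function(params, times = 0:12, noise_sd_X = 0,
                           noise_sd_S = 0, noise_sd_P = 0, relative = FALSE,
                           seed = NULL, series = c("X", "S", "P")) {
  stopifnot(inherits(params, "kinetic_params"),
            noise_sd_X >= 0, noise_sd_S >= 0, noise_sd_P >= 0)
  series <- match.arg(series, several.ok = TRUE)
  gen <- function() {
    noisy <- function(signal, sd) {
      if (sd == 0) return(signal)
      s <- if (relative) sd * abs(signal) else rep(sd, length(signal))
      signal + stats::rnorm(length(signal), 0, s)
    }
    X <- pmax(noisy(logistic_X(times, params), noise_sd_X), 0)
    S <- if ("S" %in% series) noisy(limlp_S(times, params), noise_sd_S)
    P <- if ("P" %in% series) noisy(lilp_P(times, params), noise_sd_P)
    time_course(times, X, S = S, P = P)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Built-in reference fixtures
#'
#' A packaged set of worked-example inputs for a five-factor antimicrobial
#' fermentation optimization of a marine actinomycete: the factor ranges
#' (incubation time 10-12 days, pH 7-9, temperature, sucrose 1-3 % w/v, soya
#' peptone 0.5-1.5 % w/v), fitted second-order coefficient sets for the five
#' indicator organisms (responses are agar-diffusion inhibition zones in mm),
#' and the fitted kinetic parameter sets (a shared logistic growth and
#' substrate-consumption set, with organism-specific product coefficients;
#' `P0 = 0` mm, `S0 = 20` g/L).
#'
#' Two factor-range variants are included because the source study reports
#' the temperature range both as 25-35 \eqn{^\circ}C and, in its narrative
#' and optimum, as 20-30 \eqn{^\circ}C: `factors` uses 25/30/35 and
#' `factors_alt` uses 20/25/30.
#'
#' @return A list with elements `factors`, `factors_alt` (both
#'   [design_spec()]s with `n_center = 8`), `organisms` (character vector),
#'   `models` (named list of [quadratic_model()]s), `kinetics` (named list of
#'   [kinetic_params()]), and `manifest` (data.frame naming each fixture).
#' @export
reference_fixtures <- function() {
  mk <- function(temp_levels) {
    design_spec(list(
      factor_spec("A", 10, 12),            # incubation time, days
      factor_spec("B", 7, 9),              # pH
      factor_spec("C", temp_levels[1L], temp_levels[2L]),  # temperature, degC
      factor_spec("D", 1, 3),              # sucrose, % w/v
      factor_spec("E", 0.5, 1.5)           # soya peptone, % w/v
    ), n_center = 8)
  }
  organisms <- c("saureus", "bsubtilis", "xcampestris", "paeruginosa",
                 "calbicans")
  # coefficient order: intercept; A..E; AB AC AD AE BC BD BE CD CE DE; A^2..E^2
  coefs <- list(
    saureus = c(20.924,
                0.0957321, -0.195509, 0.0896271, 0.189804, 0.0898044,
                0.00453468, -0.00453468, -0.00591517, -0.00591517, 0.0110212,
                0.0108328, 0.0108328, -0.0108328, -0.0108328, -0.0110212,
                -0.54795, -0.14795, -0.34795, -1.04795, -0.94795),
    bsubtilis = c(20.3477,
                  0.127445, 0.145469, 0.313355, 0.167851, 0.285498,
                  0.0333395, 0.0291605, -0.00675795, -0.00675795, 0.0483105,
                  0.0279083, 0.0279083, -0.0154083, -0.0154083, 0.0141895,
                  -0.545489, -0.545489, -0.945489, -0.145489, -0.345489),
    xcampestris = c(22.7623,
                    0.3, 0.10183, 0.0540524, 0.3, -0.3,
                    1.80021e-15, 2.57419e-15, 0.00777721, 0.00777721,
                    0.0019443, 1.8162e-15, 2.3339e-15, 2.2161e-15,
                    2.35407e-15, -0.0019443,
                    -0.924567, -1.12457, -0.374567, -1.12457, -1.52457),
    paeruginosa = c(19.5911,
                    5.58251e-16, 0.000670037, 0.09933, 5.20199e-16, -0.1,
                    -6.15544e-16, -8.10404e-16, 0.00284766, 0.00284766,
                    0.000711914, -5.92518e-16, -3.0522e-16, -6.59243e-16,
                    -1.44794e-15, -0.000711914,
                    -0.682226, -0.682226, -0.582226, -0.482226, -0.782226),
    calbicans = c(17.8007,
                  -0.00142264, -0.208914, 0.100091, 0.000523031, 0.409347,
                  0.00151156, -0.00151156, -0.000385869, -0.000385869,
                  -9.64674e-05, -0.00055572, -0.00055572, 0.00055572,
                  0.00055572, 9.64674e-05,
                  -0.501358, -0.151358, -0.401358, -0.301358, -0.351358)
  )
  fnames <- c("A", "B", "C", "D", "E")
  models <- lapply(coefs, function(v) {
    quadratic_model(v[1L], v[2:6], v[7:16], v[17:21], factor_names = fnames)
  })

  # shared logistic growth and substrate set; organism-specific alpha, beta
  alpha <- c(saureus = 87.224, bsubtilis = 81.246, xcampestris = 124.62,
             paeruginosa = 79.93, calbicans = 100.24)
  beta <- c(saureus = 8.8496, bsubtilis = 8.8496, xcampestris = 4.4248,
            paeruginosa = 8.8496, calbicans = 4.4248)
  kinetics <- lapply(organisms, function(org) {
    kinetic_params(mu_max = 0.7431, X0 = 0.005, Xm = 0.226,
                   gamma = 4.8774, eta = 2.566371681,
                   alpha = alpha[[org]], beta = beta[[org]],
                   S0 = 20, P0 = 0)
  })
  names(kinetics) <- organisms

  manifest <- data.frame(
    fixture = c("factors", "factors_alt",
                paste0(organisms, "_model"), paste0(organisms, "_kinetics")),
    kind = c("design_spec", "design_spec",
             rep("quadratic_model", 5L), rep("kinetic_params", 5L)),
    description = c(
      "five-factor face-centered CCD spec, temperature 25/30/35 degC",
      "variant with temperature 20/25/30 degC",
      paste("fitted second-order coefficients, inhibition zone vs", organisms),
      paste("fitted logistic + Luedeking-Piret parameters,", organisms)
    ),
    stringsAsFactors = FALSE
  )

  list(factors = mk(c(25, 35)), factors_alt = mk(c(20, 30)),
       organisms = organisms, models = models, kinetics = kinetics,
       manifest = manifest)
}
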