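# Shared fixtures and independent oracles.

# a small design with named factors A, B, ... on unit actual ranges
toy_design <- function(n = 3L, n_c = 4L) {
  specs <- lapply(seq_len(n), function(i) {
    factor_spec(LETTERS[i], low = i, high = i + 2)
  })
  generate_ccfd(design_spec(specs, n_c))
}

# random full quadratic model on n factors, coefficients in [-2, 2]
random_quadratic_model <- function(n, seed) {
  k <- 1L + n + n * (n - 1L) / 2L + n
  co <- with_seed_helper(seed, stats::runif(k, -2, 2))
  quadratic_model(co[1L], co[1L + seq_len(n)],
                  co[1L + n + seq_len(n * (n - 1L) / 2L)],
                  co[(1L + n + n * (n - 1L) / 2L) + seq_len(n)],
                  factor_names = LETTERS[seq_len(n)])
}

with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# random valid kinetic parameter set, spanning realistic batch ranges
random_kinetic_params <- function(seed) {
  with_seed_helper(seed, {
    Xm <- stats::runif(1, 0.1, 5)
    kinetic_params(
      mu_max = stats::runif(1, 0.2, 1.5),
      X0 = stats::runif(1, 0.002, 0.05) * Xm,
      Xm = Xm,
      gamma = stats::runif(1, 0, 8),
      eta = stats::runif(1, 0, 4),
      alpha = stats::runif(1, 0, 120),
      beta = stats::runif(1, 0, 10),
      S0 = 20, P0 = 0
    )
  })
}

# noise scale for recovery studies: a fraction of each series' amplitude
# over a 12-day batch (growth range, substrate consumed, final zone size)
kin_noise_sigmas <- function(p, frac, t_end = 12) {
  c(X = frac * (p$Xm - p$X0),
    S = frac * (p$S0 - suppressWarnings(limlp_S(t_end, p))),
    P = frac * (lilp_P(t_end, p) - p$P0))
}

# independent oracle: adaptive integration of the rate equations
#   dX/dt = mu X (1 - X/Xm)
#   dS/dt = -(gamma dX/dt + eta X)
#   dP/dt = alpha dX/dt + beta X
ode_oracle <- function(p, times) {
  rhs <- function(t, y, parms) {
    dX <- p$mu_max * y[1L] * (1 - y[1L] / p$Xm)
    list(c(dX, -(p$gamma * dX + p$eta * y[1L]), p$alpha * dX + p$beta * y[1L]))
  }
  out <- deSolve::ode(y = c(X = p$X0, S = p$S0, P = p$P0), times = times,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  as.data.frame(out)
}

# the reference five-factor fixture set, shared across files
fx <- reference_fixtures()
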