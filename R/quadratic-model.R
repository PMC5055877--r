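# Second-order (quadratic) response-surface model on coded factors:
#   Y = b0 + sum_i bi xi + sum_{i<j} bij xi xj + sum_i bii xi^2

#' Construct a quadratic response-surface model
#'
#' Holds the coefficients of a full second-order polynomial on coded factors:
#' intercept, one linear term per factor, one interaction term per unordered
#' factor pair (pairs ordered lexicographically by position), and one pure
#' quadratic term per factor — `1 + n + n(n-1)/2 + n` coefficients for `n`
#' factors (21 for n = 5).
#'
#' @param intercept Intercept coefficient.
#' @param linear Named or ordered numeric vector, one entry per factor.
#' @param interaction Numeric vector of pairwise interaction coefficients in
#'   lexicographic pair order (1-2, 1-3, ..., (n-1)-n).
#' @param quadratic Numeric vector of squared-term coefficients, one per factor.
#' @param factor_names Character vector of factor labels.
#' @return An object of class `quadratic_model`.
#' @export
quadratic_model <- function(intercept, linear, interaction, quadratic,
                            factor_names = names(linear)) {
  n <- length(linear)
  if (is.null(factor_names)) factor_names <- paste0("x", seq_len(n))
  stopifnot(length(factor_names) == n, n >= 1L,
            length(quadratic) == n,
            length(interaction) == n * (n - 1L) / 2L,
            length(intercept) == 1L)
  coef <- c(intercept, linear, interaction, quadratic)
  if (!all(is.finite(coef))) stop("non-finite coefficient", call. = FALSE)
  names(coef) <- quadratic_term_names(factor_names)
  structure(list(coefficients = unname(coef), terms = names(coef),
                 factor_names = factor_names, n_factors = n),
            class = "quadratic_model")
}

# Canonical term order: intercept, linear, lexicographic pairs, squares.
quadratic_term_names <- function(factor_names) {
  n <- length(factor_names)
  pairs <- character(0)
  if (n >= 2L) {
    idx <- utils::combn(n, 2L)
    pairs <- paste0(factor_names[idx[1L, ]], ":", factor_names[idx[2L, ]])
  }
  c("(Intercept)", factor_names, pairs, paste0(factor_names, "^2"))
}

#' @export
print.quadratic_model <- function(x, digits = 6, ...) {
  cat(sprintf("<quadratic_model> %d factors (%s), %d terms\n",
              x$n_factors, paste(x$factor_names, collapse = ", "),
              length(x$coefficients)))
  print(stats::setNames(signif(x$coefficients, digits), x$terms))
  invisible(x)
}

#' @export
coef.quadratic_model <- function(object, ...) {
  stats::setNames(object$coefficients, object$terms)
}

#' Expand coded points into the quadratic model matrix
#'
#' Columns are ordered: intercept, linear terms, pairwise interactions in
#' lexicographic pair order, then squared terms. Used both for fitting and
#' for prediction so the two cannot disagree on term order.
#'
#' @param design A `ccfd_design`, a coded matrix, or a coded point (vector).
#' @param factor_names Factor labels when `design` is a bare matrix/vector.
#' @return Numeric model matrix with one row per run and named columns.
#' @export
build_design_matrix <- function(design, factor_names = NULL) {
  if (inherits(design, "ccfd_design")) {
    x <- coded_matrix(design)
  } else if (is.numeric(design) && is.null(dim(design))) {
    x <- matrix(design, nrow = 1L,
                dimnames = list(NULL, factor_names))
  } else {
    x <- as.matrix(design)
    if (!is.null(factor_names)) colnames(x) <- factor_names
  }
  n <- ncol(x)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(n))
  cols <- list(`(Intercept)` = rep(1, nrow(x)))
  for (i in seq_len(n)) cols[[nm[i]]] <- x[, i]
  if (n >= 2L) {
    idx <- utils::combn(n, 2L)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1L, k]; j <- idx[2L, k]
      cols[[paste0(nm[i], ":", nm[j])]] <- x[, i] * x[, j]
    }
  }
  for (i in seq_len(n)) cols[[paste0(nm[i], "^2")]] <- x[, i]^2
  mm <- do.call(cbind, cols)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dep <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop("rank-deficient quadratic model matrix; dependent columns: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  mm
}

#' Predict from a quadratic model at coded points
#'
#' Evaluates the second-order polynomial term by term; at the all-zero coded
#' point the prediction equals the intercept exactly.
#'
#' @param object A [quadratic_model()].
#' @param newdata Coded point (numeric vector) or matrix/data.frame of coded
#'   points, one row per point.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.quadratic_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(newdata) != object$n_factors) {
      stop(sprintf("coded point has length %d, model has %d factors",
                   length(newdata), object$n_factors), call. = FALSE)
    }
    newdata <- matrix(newdata, nrow = 1L)
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_factors) {
    stop(sprintf("newdata has %d columns, model has %d factors",
                 ncol(newdata), object$n_factors), call. = FALSE)
  }
  colnames(newdata) <- object$factor_names
  mm <- model_matrix_no_rank_check(newdata)
  unname(drop(mm %*% object$coefficients))
}

# prediction must not fail on e.g. a single point, where columns collapse
model_matrix_no_rank_check <- function(x) {
  n <- ncol(x)
  nm <- colnames(x)
  cols <- list(rep(1, nrow(x)))
  for (i in seq_len(n)) cols[[length(cols) + 1L]] <- x[, i]
  if (n >= 2L) {
    idx <- utils::combn(n, 2L)
    for (k in seq_len(ncol(idx))) {
      cols[[length(cols) + 1L]] <- x[, idx[1L, k]] * x[, idx[2L, k]]
    }
  }
  for (i in seq_len(n)) cols[[length(cols) + 1L]] <- x[, i]^2
  mm <- do.call(cbind, cols)
  colnames(mm) <- quadratic_term_names(nm)
  mm
}

# Split the coefficient vector into (b, Q) with Y = b0 + b'x + x'Qx,
# Q symmetric: Q_ii = b_ii, Q_ij = b_ij / 2.
quad_form_parts <- function(model) {
  n <- model$n_factors
  co <- model$coefficients
  b0 <- co[1L]
  b <- co[1L + seq_len(n)]
  Q <- diag(co[(1L + n + n * (n - 1L) / 2L) + seq_len(n)], n)
  if (n >= 2L) {
    idx <- utils::combn(n, 2L)
    off <- co[1L + n + seq_len(ncol(idx))]
    for (k in seq_len(ncol(idx))) {
      Q[idx[1L, k], idx[2L, k]] <- off[k] / 2
      Q[idx[2L, k], idx[1L, k]] <- off[k] / 2
    }
  }
  list(b0 = b0, b = b, Q = Q)
}

#' Maximize a quadratic model over the coded cube
#'
#' Solves the stationary condition of the fitted surface; if the stationary
#' point is an interior maximum of the cube `[-1, 1]^n` it is returned
#' directly. Otherwise the surface is maximized by deterministic multi-start
#' box-constrained quasi-Newton search (corner, center, projected-stationary
#' and seeded random starts). Ties are broken toward the lexicographically
#' smallest coded point.
#'
#' @param model A [quadratic_model()].
#' @param n_random Number of random starts (seeded; deterministic).
#' @param seed Seed for the random starts.
#' @return List with `point` (coded optimum), `value` (predicted response at
#'   the optimum) and `classification` (`"interior stationary max"`,
#'   `"boundary max"` or `"saddle-adjusted"`).
#' @export
optimum_on_cube <- function(model, n_random = 20L, seed = 101L) {
  stopifnot(inherits(model, "quadratic_model"))
  n <- model$n_factors
  qf <- quad_form_parts(model)
  f <- function(x) qf$b0 + sum(qf$b * x) + drop(crossprod(x, qf$Q %*% x))
  grad <- function(x) qf$b + 2 * drop(qf$Q %*% x)

  ev <- eigen(qf$Q, symmetric = TRUE, only.values = TRUE)$values
  stationary <- NULL
  if (min(abs(ev)) > 1e-10) stationary <- drop(solve(-2 * qf$Q, qf$b))
  if (!is.null(stationary) && max(ev) < -1e-10 &&
      all(abs(stationary) <= 1 + 1e-12)) {
    pt <- pmin(1, pmax(-1, stationary))
    return(list(point = stats::setNames(pt, model$factor_names),
                value = f(pt), classification = "interior stationary max"))
  }

  starts <- list(rep(0, n))
  if (!is.null(stationary)) starts <- c(starts, list(pmin(1, pmax(-1, stationary))))
  corners <- as.matrix(expand.grid(rep(list(c(-1, 1)), min(n, 6L))))
  if (n > 6L) corners <- cbind(corners, matrix(0, nrow(corners), n - 6L))
  starts <- c(starts, split(corners, row(corners)))
  rand <- with_seed(seed, matrix(stats::runif(n_random * n, -1, 1), n_random, n))
  starts <- c(starts, split(rand, row(rand)))

  best <- NULL
  for (s in starts) {
    res <- stats::optim(as.numeric(s), fn = function(x) -f(x),
                        gr = function(x) -grad(x),
                        method = "L-BFGS-B", lower = rep(-1, n),
                        upper = rep(1, n),
                        control = list(factr = 1e3, maxit = 500L))
    cand <- list(point = res$par, value = -res$value)
    if (is.null(best) || cand$value > best$value + 1e-9 ||
        (abs(cand$value - best$value) <= 1e-9 &&
         lex_less(cand$point, best$point))) {
      best <- cand
    }
  }
  on_boundary <- any(abs(abs(best$point) - 1) < 1e-6)
  best$point[abs(best$point) < 1e-9] <- 0
  list(point = stats::setNames(best$point, model$factor_names),
       value = best$value,
       classification = if (on_boundary) "boundary max" else "saddle-adjusted")
}

lex_less <- function(a, b, tol = 1e-9) {
  d <- a - b
  k <- which(abs(d) > tol)
  length(k) > 0L && d[k[1L]] < 0
}

#' Predicted-response grid over a factor pair
#'
#' Evaluates the model on a regular coded grid over `[-1, 1]^2` for the two
#' factors in `pair`, all remaining factors held at `fixed_point` (default:
#' the center). This is the numerical content of the usual 3-D response
#' surface plots.
#'
#' @param model A [quadratic_model()].
#' @param pair Length-2 vector of factor names or indices (distinct).
#' @param fixed_point Coded values for all factors; entries for the varied
#'   pair are ignored. Defaults to all zeros.
#' @param grid_size Number of grid nodes per axis.
#' @return `grid_size x grid_size` matrix of predictions; rows index the first
#'   factor of the pair, columns the second. Axis values are in the dimnames
#'   and in attributes `x1`/`x2`; `as.data.frame()` on the result (via
#'   [surface_grid_long()]) gives the long format.
#' @export
surface_grid <- function(model, pair, fixed_point = rep(0, model$n_factors),
                         grid_size = 21L) {
  stopifnot(inherits(model, "quadratic_model"), length(pair) == 2L)
  if (is.character(pair)) pair <- match(pair, model$factor_names)
  if (anyNA(pair) || pair[1L] == pair[2L]) {
    stop("'pair' must name two distinct model factors", call. = FALSE)
  }
  stopifnot(length(fixed_point) == model$n_factors)
  g <- seq(-1, 1, length.out = grid_size)
  pts <- matrix(rep(fixed_point, each = grid_size^2), ncol = model$n_factors)
  pts[, pair[1L]] <- rep(g, times = grid_size)
  pts[, pair[2L]] <- rep(g, each = grid_size)
  z <- matrix(predict(model, pts), grid_size, grid_size)
  dimnames(z) <- list(format(g, digits = 4), format(g, digits = 4))
  attr(z, "x1") <- g
  attr(z, "x2") <- g
  attr(z, "factors") <- model$factor_names[pair]
  z
}

#' @rdname surface_grid
#' @param grid A matrix returned by `surface_grid()`.
#' @export
surface_grid_long <- function(grid) {
  fx <- attr(grid, "factors")
  out <- expand.grid(x1 = attr(grid, "x1"), x2 = attr(grid, "x2"))
  names(out) <- fx
  out$value <- as.vector(grid)
  out
}
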