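# Face-centered central composite designs over coded factors.

#' Define a process factor and its coded levels
#'
#' A factor is described by the actual values taken at the three coded levels
#' of a face-centered design: `low` (-1), `center` (0) and `high` (+1). The
#' coded transform is the usual linear map, so the center is expected to sit
#' midway between `low` and `high`; an off-center value is allowed (the map
#' stays linear in the half-range) but triggers a warning.
#'
#' @param name Character label, e.g. `"pH"`.
#' @param low Actual value at coded level -1.
#' @param high Actual value at coded level +1.
#' @param center Actual value at coded level 0. Defaults to the midpoint.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("incubation_days", 10, 12)
#' @export
factor_spec <- function(name, low, high, center = (low + high) / 2) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (v in list(low = low, center = center, high = high)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("factor levels must be finite numeric scalars", call. = FALSE)
    }
  }
  if (!(low < center && center < high)) {
    stop(sprintf("factor '%s': need low < center < high (got %g, %g, %g)",
                 name, low, center, high), call. = FALSE)
  }
  mid <- (low + high) / 2
  if (abs(center - mid) > 1e-8 * (high - low)) {
    warning(sprintf("factor '%s': center %g is not the midpoint of [%g, %g]",
                    name, center, low, high), call. = FALSE)
  }
  structure(list(name = name, low = low, center = center, high = high),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s: -1 = %g, 0 = %g, +1 = %g\n",
              x$name, x$low, x$center, x$high))
  invisible(x)
}

#' Define a central composite design
#'
#' @param factors List of [factor_spec()] objects (at least two).
#' @param n_center Number of replicated center points (at least one).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(factors, n_center) {
  if (inherits(factors, "factor_spec")) factors <- list(factors)
  if (!is.list(factors) || length(factors) < 2L ||
      !all(vapply(factors, inherits, logical(1), "factor_spec"))) {
    stop("'factors' must be a list of >= 2 factor_spec objects", call. = FALSE)
  }
  nm <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("factor names must be unique", call. = FALSE)
  n_center <- assert_count(n_center, "n_center", min = 1L)
  structure(list(factors = factors, n_center = n_center),
            class = "design_spec")
}

# integer-valued scalar check shared by count_runs() and design_spec()
assert_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop(sprintf("'%s' must be an integer >= %d", what, min), call. = FALSE)
  }
  as.integer(x)
}

#' Number of runs in a central composite design
#'
#' A full central composite design on `n` factors has `2^n` factorial points,
#' `2n` axial (star) points and `n_c` replicated center points, for
#' `N = 2^n + 2n + n_c` runs in total.
#'
#' @param n Number of factors.
#' @param n_c Number of center-point replicates.
#' @return Integer run count.
#' @examples
#' count_runs(5, 8)  # 50
#' @export
count_runs <- function(n, n_c) {
  n <- assert_count(n, "n", min = 1L)
  n_c <- assert_count(n_c, "n_c", min = 0L)
  as.integer(2^n + 2L * n + n_c)
}

#' Convert between actual and coded factor values
#'
#' The coded value is `(actual - center) / half_range` with
#' `half_range = (high - low) / 2`, so the design levels low/center/high map
#' to -1/0/+1. `decode_factor()` is the exact inverse.
#'
#' @param actual,coded Numeric vector of values to convert.
#' @param spec A [factor_spec()].
#' @return Numeric vector of the same length.
#' @examples
#' sp <- factor_spec("time", 10, 12)
#' code_factor(12, sp)     # +1
#' decode_factor(-0.5, sp) # 10.5
#' @export
code_factor <- function(actual, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  half <- (spec$high - spec$low) / 2
  if (half <= 0) stop("zero half-range in factor spec", call. = FALSE)
  (actual - spec$center) / half
}

#' @rdname code_factor
#' @export
decode_factor <- function(coded, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  half <- (spec$high - spec$low) / 2
  if (half <= 0) stop("zero half-range in factor spec", call. = FALSE)
  spec$center + coded * half
}

#' Generate a face-centered central composite design
#'
#' Builds the full design table: all `2^n` factorial combinations at coded
#' levels +/-1, `2n` axial points with a single coordinate at +/-1 (axial
#' distance 1, i.e. face-centered, so every factor has exactly three levels),
#' and `n_c` center replicates. Canonical order is factorial block, axial
#' block, center block; set `randomize = TRUE` with a `seed` for a
#' reproducible random run order.
#'
#' @param spec A [design_spec()].
#' @param randomize Permute the run order?
#' @param seed Integer seed used only when `randomize = TRUE`.
#' @return A `data.frame` of class `ccfd_design` with columns `run`, `class`
#'   (factorial/axial/center), one coded column per factor (named after the
#'   factor) and one actual column per factor (suffix `_actual`).
#' @examples
#' sp <- design_spec(list(factor_spec("A", 10, 12), factor_spec("B", 7, 9)),
#'                   n_center = 1)
#' generate_ccfd(sp)
#' @export
generate_ccfd <- function(spec, randomize = FALSE, seed = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  n <- length(spec$factors)
  nm <- vapply(spec$factors, `[[`, character(1), "name")

  factorial <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  axial <- matrix(0, nrow = 2L * n, ncol = n)
  for (i in seq_len(n)) {
    axial[2L * i - 1L, i] <- -1
    axial[2L * i, i] <- 1
  }
  center <- matrix(0, nrow = spec$n_center, ncol = n)

  coded <- rbind(factorial, axial, center)
  dimnames(coded) <- list(NULL, nm)
  class_lab <- rep(c("factorial", "axial", "center"),
                   c(nrow(factorial), nrow(axial), nrow(center)))

  if (isTRUE(randomize)) {
    if (is.null(seed)) stop("randomize = TRUE requires a seed", call. = FALSE)
    ord <- with_seed(seed, sample.int(nrow(coded)))
    coded <- coded[ord, , drop = FALSE]
    class_lab <- class_lab[ord]
  }

  actual <- coded
  for (i in seq_len(n)) actual[, i] <- decode_factor(coded[, i], spec$factors[[i]])
  colnames(actual) <- paste0(nm, "_actual")

  out <- data.frame(run = seq_len(nrow(coded)), class = class_lab,
                    coded, actual, check.names = FALSE,
                    stringsAsFactors = FALSE)
  structure(out, class = c("ccfd_design", "data.frame"),
            factor_names = nm, spec = spec)
}

#' Coded coordinates of a design
#'
#' @param design A `ccfd_design` (or any data.frame holding the coded columns).
#' @param factor_names Factor column names; taken from the design attribute
#'   when present.
#' @return Numeric matrix, one column per factor.
#' @export
coded_matrix <- function(design, factor_names = attr(design, "factor_names")) {
  if (is.null(factor_names)) {
    stop("supply 'factor_names' for a plain data.frame", call. = FALSE)
  }
  missing <- setdiff(factor_names, colnames(design))
  if (length(missing)) {
    stop("design lacks coded columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(design[, factor_names, drop = FALSE])
}

# Run `expr` under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
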