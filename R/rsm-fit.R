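# OLS fitting of the second-order model on coded factors, with the ANOVA
# layout customary in response-surface work: per-term partial sums of
# squares, residual split into lack-of-fit and pure (replicate) error, and
# the R-squared family of diagnostics.

#' Fit diagnostics for a regression model
#'
#' Computes the usual response-surface goodness-of-fit family from observed
#' and predicted values:
#' \itemize{
#'   \item `r2 = 1 - SS_res / SS_tot`
#'   \item `adj_r2 = 1 - (1 - r2) (n - 1) / (n - p)`
#'   \item `press = sum((e_i / (1 - h_i))^2)` (needs `leverage`)
#'   \item `pred_r2 = 1 - press / SS_tot`
#'   \item `std_dev = sqrt(SS_res / (n - p))` (root residual mean square)
#'   \item `cv_pct = 100 * std_dev / mean(observed)`
#'   \item `rmse = sqrt(SS_res / n)`
#'   \item `aad_pct = (100 / n) * sum(|obs - pred| / obs)`
#' }
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param p_terms Number of model terms including the intercept.
#' @param leverage Hat-matrix diagonal, needed for PRESS / predicted
#'   R-squared; omit to skip those two.
#' @return An object of class `fit_summary` (a named list of the quantities
#'   above plus `n` and `p_terms`).
#' @export
fit_metrics <- function(observed, predicted, p_terms, leverage = NULL) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  e <- observed - predicted
  ss_res <- sum(e^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  adj_r2 <- if (n > p_terms && ss_tot > 0) {
    1 - (1 - r2) * (n - 1) / (n - p_terms)
  } else NA_real_
  std_dev <- if (n > p_terms) sqrt(ss_res / (n - p_terms)) else NA_real_
  press <- pred_r2 <- NA_real_
  if (!is.null(leverage)) {
    stopifnot(length(leverage) == n)
    if (any(leverage > 1 - 1e-10)) {
      warning("leverage of 1: PRESS undefined (a point fits itself exactly)",
              call. = FALSE)
    } else {
      press <- sum((e / (1 - leverage))^2)
      pred_r2 <- if (ss_tot > 0) 1 - press / ss_tot else NA_real_
    }
  }
  aad_pct <- if (any(observed == 0)) {
    warning("observed value of 0: AAD% undefined", call. = FALSE)
    NA_real_
  } else 100 * mean(abs(e) / abs(observed))
  structure(list(
    r2 = r2, adj_r2 = adj_r2, pred_r2 = pred_r2, press = press,
    std_dev = std_dev,
    cv_pct = if (mean(observed) != 0) 100 * std_dev / mean(observed) else NA_real_,
    rmse = sqrt(ss_res / n), aad_pct = aad_pct,
    n = n, p_terms = p_terms
  ), class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, digits = 4, ...) {
  cat("<fit_summary>\n")
  flds <- c("r2", "adj_r2", "pred_r2", "std_dev", "cv_pct", "rmse",
            "aad_pct", "press")
  for (f in flds) cat(sprintf("  %-8s %s\n", f, format(signif(x[[f]], digits))))
  invisible(x)
}

#' Fit the quadratic response-surface model by ordinary least squares
#'
#' Fits the full second-order polynomial on the design's coded factors. The
#' ANOVA table reports partial (type III) per-term sums of squares; on the
#' orthogonal blocks of a face-centered composite design these coincide with
#' the sequential values for linear and interaction terms. The residual is
#' split into lack-of-fit and pure error using exact replicate coded rows
#' (the center replicates, in a standard CCD).
#'
#' @param design A `ccfd_design` (or data.frame carrying coded columns plus a
#'   `factor_names` attribute).
#' @param response Numeric response, one value per run.
#' @return An object of class `rsm_fit`: list with elements `model`
#'   ([quadratic_model()]), `summary` ([fit_metrics()] output), `anova`
#'   (data.frame), `lof` (lack-of-fit decomposition), `fitted`, `residuals`,
#'   `leverage` and the underlying `lm` object.
#' @export
fit_quadratic <- function(design, response) {
  x <- coded_matrix(design)
  n <- nrow(x)
  if (length(response) != n) {
    stop("response length must equal the number of runs", call. = FALSE)
  }
  if (anyNA(response)) stop("response contains missing values", call. = FALSE)

  if (stats::sd(response) == 0) {
    warning("zero response variance: returning intercept-only model",
            call. = FALSE)
    k <- ncol(x)
    model <- quadratic_model(mean(response), rep(0, k),
                             rep(0, k * (k - 1L) / 2L), rep(0, k),
                             factor_names = colnames(x))
    summ <- fit_metrics(response, rep(mean(response), n), p_terms = 1L)
    return(structure(list(model = model, summary = summ, anova = NULL,
                          lof = NULL, fitted = rep(mean(response), n),
                          residuals = rep(0, n), leverage = NULL, lm = NULL),
                     class = "rsm_fit"))
  }

  k <- ncol(x)
  p <- 1L + 2L * k + k * (k - 1L) %/% 2L
  if (n <= p) {
    stop(sprintf("need more runs (%d) than model terms (%d)", n, p),
         call. = FALSE)
  }
  mm <- build_design_matrix(x)
  df <- as.data.frame(mm[, -1L, drop = FALSE])
  safe <- paste0("T", seq_len(ncol(df)))  # syntactic stand-ins for lm
  term_labels <- colnames(mm)[-1L]
  names(df) <- safe
  df$.y <- response
  fit <- stats::lm(.y ~ ., data = df)

  co <- stats::coef(fit)
  k <- ncol(x)
  model <- quadratic_model(co[[1L]], co[1L + seq_len(k)],
                           co[1L + k + seq_len(k * (k - 1L) / 2L)],
                           co[(1L + k + k * (k - 1L) / 2L) + seq_len(k)],
                           factor_names = colnames(x))

  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  summ <- fit_metrics(response, stats::fitted(fit), p_terms = p, leverage = h)

  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((response - mean(response))^2)
  ms_res <- ss_res / (n - p)
  # suppressWarnings: summary.lm complains about "essentially perfect fit"
  # on noise-free synthetic responses, where the SEs are legitimately ~0
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  tt <- co / se
  ss_term <- (tt[-1L])^2 * ms_res  # partial SS for 1-df terms
  f_term <- ss_term / ms_res
  p_term <- stats::pf(f_term, 1, n - p, lower.tail = FALSE)

  lof <- lack_of_fit_split(x, response, ss_res, df_res = n - p)

  anova_tab <- data.frame(
    source = c("Model", term_labels, "Residual", "Lack of fit", "Pure error",
               "Total"),
    ss = c(ss_tot - ss_res, unname(ss_term), ss_res, lof$ss_lof, lof$ss_pe,
           ss_tot),
    df = c(p - 1L, rep(1L, length(term_labels)), n - p, lof$df_lof, lof$df_pe,
           n - 1L),
    stringsAsFactors = FALSE
  )
  anova_tab$ms <- anova_tab$ss / anova_tab$df
  f_model <- ((ss_tot - ss_res) / (p - 1L)) / ms_res
  anova_tab$f <- c(f_model, unname(f_term), NA, lof$f, NA, NA)
  anova_tab$p <- c(stats::pf(f_model, p - 1L, n - p, lower.tail = FALSE),
                   unname(p_term), NA, lof$p, NA, NA)

  structure(list(model = model, summary = summ, anova = anova_tab, lof = lof,
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit), leverage = h, lm = fit),
            class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, digits = 4, ...) {
  cat("Quadratic response-surface fit\n")
  print(x$model, digits = digits)
  if (!is.null(x$anova)) {
    cat("\nANOVA (partial SS):\n")
    tab <- x$anova
    tab[-1L] <- lapply(tab[-1L], function(v) signif(v, digits))
    print(tab, row.names = FALSE)
  }
  cat("\n")
  print(x$summary, digits = digits)
  invisible(x)
}

# Pure error from exact replicate coded rows; lack of fit as the remainder.
lack_of_fit_split <- function(x, response, ss_res, df_res) {
  key <- apply(x, 1L, paste, collapse = "\r")
  groups <- split(response, key)
  reps <- groups[lengths(groups) >= 2L]
  if (!length(reps)) {
    return(list(ss_pe = NA_real_, df_pe = NA_integer_, ss_lof = NA_real_,
                df_lof = NA_integer_, f = NA_real_, p = NA_real_,
                computable = FALSE, degenerate = FALSE))
  }
  ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), numeric(1)))
  df_pe <- sum(vapply(reps, length, integer(1))) - length(reps)
  ss_lof <- max(ss_res - ss_pe, 0)
  df_lof <- df_res - df_pe
  if (df_lof <= 0L) {
    return(list(ss_pe = ss_pe, df_pe = df_pe, ss_lof = ss_lof, df_lof = df_lof,
                f = NA_real_, p = NA_real_, computable = FALSE,
                degenerate = FALSE))
  }
  if (ss_pe == 0) {
    # identical replicates everywhere: pure-error MS is 0, F undefined
    return(list(ss_pe = 0, df_pe = df_pe, ss_lof = ss_lof, df_lof = df_lof,
                f = NA_real_, p = NA_real_, computable = TRUE,
                degenerate = TRUE))
  }
  f <- (ss_lof / df_lof) / (ss_pe / df_pe)
  list(ss_pe = ss_pe, df_pe = df_pe, ss_lof = ss_lof, df_lof = df_lof,
       f = f, p = stats::pf(f, df_lof, df_pe, lower.tail = FALSE),
       computable = TRUE, degenerate = FALSE)
}

#' Lack-of-fit test for a fitted response-surface model
#'
#' Partitions the residual sum of squares of a fitted model into pure error
#' (within-replicate variation at identically coded runs) and lack of fit,
#' and tests lack of fit against pure error with an F ratio.
#'
#' @param design The design used for fitting.
#' @param response The response used for fitting.
#' @param fit An `rsm_fit`, or any model accepted by `predict()` on the
#'   coded matrix together with `p_terms`.
#' @param p_terms Model term count; taken from `fit` when it is an `rsm_fit`.
#' @return List with `ss_lof`, `df_lof`, `ss_pe`, `df_pe`, `f`, `p`, and
#'   flags `computable` (FALSE when the design has no replicates or no
#'   lack-of-fit degrees of freedom) and `degenerate` (pure error exactly 0).
#' @export
lack_of_fit <- function(design, response, fit, p_terms = NULL) {
  x <- coded_matrix(design)
  if (inherits(fit, "rsm_fit")) {
    pred <- fit$fitted
    p_terms <- fit$summary$p_terms
  } else {
    if (is.null(p_terms)) stop("supply 'p_terms' with a bare model", call. = FALSE)
    pred <- predict(fit, x)
  }
  ss_res <- sum((response - pred)^2)
  lack_of_fit_split(x, response, ss_res, df_res = nrow(x) - p_terms)
}

#' Sequential model sums of squares across nested polynomial tiers
#'
#' Fits the nested sequence mean, linear, two-factor-interaction (2FI),
#' quadratic, cubic on coded factors and reports each tier's incremental sum
#' of squares, with `F = (delta SS / delta df) / MS_residual` of the larger
#' (current) model. On a three-level face-centered design the pure-cubic
#' columns `x_i^3` are aliased with the linear columns and the cubic tier
#' retains only the estimable mixed terms `x_i x_j^2`; aliased columns are
#' dropped and reported.
#'
#' @inheritParams fit_quadratic
#' @return data.frame of class `sequential_ss` with one row per tier:
#'   `tier`, `ss` (incremental), `df`, `ms`, `f`, `p`, `r2` (cumulative),
#'   plus an `aliased` attribute listing dropped cubic columns.
#' @export
sequential_model_ss <- function(design, response) {
  x <- coded_matrix(design)
  n <- nrow(x)
  k <- ncol(x)
  nm <- colnames(x)
  mm <- build_design_matrix(x)
  lin_cols <- 1L + seq_len(k)
  int_cols <- if (k >= 2L) 1L + k + seq_len(k * (k - 1L) / 2L) else integer(0)
  quad_cols <- (1L + k + length(int_cols)) + seq_len(k)

  cubic <- list()
  for (i in seq_len(k)) {
    cubic[[paste0(nm[i], "^3")]] <- x[, i]^3
    for (j in seq_len(k)) if (j != i) {
      cubic[[paste0(nm[i], ":", nm[j], "^2")]] <- x[, i] * x[, j]^2
    }
  }
  cubic <- do.call(cbind, cubic)

  tiers <- list(
    mean = mm[, 1L, drop = FALSE],
    linear = mm[, c(1L, lin_cols), drop = FALSE],
    `2FI` = mm[, c(1L, lin_cols, int_cols), drop = FALSE],
    quadratic = mm[, c(1L, lin_cols, int_cols, quad_cols), drop = FALSE],
    cubic = cbind(mm, cubic)
  )

  ss_tot <- sum((response - mean(response))^2)
  rows <- list()
  aliased <- character(0)
  # residual SS of the empty model is the uncorrected total; the mean tier
  # then removes the correction-for-the-mean SS
  prev_ss_res <- sum(response^2)
  prev_rank <- 0L
  for (tier in names(tiers)) {
    z <- tiers[[tier]]
    qz <- qr(z)
    rank <- qz$rank
    if (rank < ncol(z)) {
      aliased <- union(aliased, colnames(z)[qz$pivot[(rank + 1L):ncol(z)]])
    }
    res <- qr.resid(qz, response)
    ss_res <- sum(res^2)
    d_ss <- prev_ss_res - ss_res
    d_df <- rank - prev_rank
    df_res <- n - rank
    ms_res <- if (df_res > 0L) ss_res / df_res else NA_real_
    f <- if (d_df > 0L && df_res > 0L && ms_res > 0) (d_ss / d_df) / ms_res else NA_real_
    pval <- if (is.finite(f)) stats::pf(f, d_df, df_res, lower.tail = FALSE) else NA_real_
    rows[[tier]] <- data.frame(
      tier = tier, ss = d_ss, df = d_df,
      ms = if (d_df > 0L) d_ss / d_df else NA_real_,
      f = f, p = pval,
      r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      stringsAsFactors = FALSE
    )
    prev_ss_res <- ss_res
    prev_rank <- rank
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "aliased") <- aliased
  class(out) <- c("sequential_ss", "data.frame")
  out
}
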