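# Delimited-text I/O. All tables are comma-separated UTF-8 with a header row.

#' Read factor specifications from a config file
#'
#' Accepts either a YAML file with a top-level `factors` list (entries with
#' keys `name`, `low`, `high` and optional `center`) or a CSV file with
#' columns `name`, `low`, `high` and optional `center`.
#'
#' @param path File path (`.yml`/`.yaml` or `.csv`).
#' @return List of [factor_spec()] objects.
#' @export
read_factor_specs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    cfg <- yaml::read_yaml(path)
    entries <- if (!is.null(cfg$factors)) cfg$factors else cfg
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    entries <- split(tab, seq_len(nrow(tab)))
  }
  lapply(entries, function(e) {
    if (is.null(e$name) || is.null(e$low) || is.null(e$high)) {
      stop("each factor needs 'name', 'low' and 'high'", call. = FALSE)
    }
    if (is.null(e$center)) {
      factor_spec(e$name, e$low, e$high)
    } else {
      factor_spec(e$name, e$low, e$high, center = e$center)
    }
  })
}

#' Write and read design tables
#'
#' The on-disk format is CSV with columns `run`, `class`, one coded column
#' per factor (named after the factor) and one `_actual` column per factor.
#'
#' @param design A `ccfd_design`.
#' @param path Output/input file path.
#' @return `write_design()` returns `path` invisibly; `read_design()` returns
#'   a `ccfd_design`-classed data.frame (factor names recovered from the
#'   `_actual` column headers).
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "ccfd_design"))
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  actual_cols <- grep("_actual$", names(tab), value = TRUE)
  fn <- sub("_actual$", "", actual_cols)
  missing <- setdiff(fn, names(tab))
  if (!length(fn) || length(missing)) {
    stop("not a design table: expected paired coded and '_actual' columns",
         call. = FALSE)
  }
  structure(tab, class = c("ccfd_design", "data.frame"), factor_names = fn)
}

#' Write and read batch time-courses
#'
#' CSV with columns `time_days`, `biomass_g_per_L` and optionally
#' `substrate_g_per_L`, `product_mm`.
#'
#' @param tc A [time_course()].
#' @param path File path.
#' @return `write_time_course()` returns `path` invisibly;
#'   `read_time_course()` returns a [time_course()].
#' @export
write_time_course <- function(tc, path) {
  stopifnot(inherits(tc, "data.frame"), !is.null(tc$time), !is.null(tc$X))
  out <- data.frame(time_days = tc$time, biomass_g_per_L = tc$X)
  if (!is.null(tc$S)) out$substrate_g_per_L <- tc$S
  if (!is.null(tc$P)) out$product_mm <- tc$P
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_time_course
#' @export
read_time_course <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_days", "biomass_g_per_L")
  if (!all(need %in% names(tab))) {
    stop("time-course file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(diff(tab$time_days) <= 0)) {
    stop("time column must be strictly increasing", call. = FALSE)
  }
  time_course(tab$time_days, tab$biomass_g_per_L,
              S = tab$substrate_g_per_L, P = tab$product_mm)
}
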