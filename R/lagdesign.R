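# calendar-aligned lagged predictor/outcome structures

# per-subject series on the complete calendar grid (NA on skipped days)
panel_series <- function(panel, vars) {
  stopifnot(all(c("subject_id", "date") %in% names(panel)),
            all(vars %in% names(panel)))
  split_idx <- split(seq_len(nrow(panel)), panel$subject_id)
  lapply(split_idx, function(ix) {
    d <- panel$date[ix]
    day <- as.integer(d - min(d)) + 1L
    Tn <- max(day)
    M <- matrix(NA_real_, Tn, length(vars),
                dimnames = list(NULL, vars))
    for (v in vars) M[day, v] <- panel[[v]][ix]
    list(dates = seq(min(d), by = 1, length.out = Tn), M = M)
  })
}

#' Build a within-subject calendar-aligned lag design
#'
#' For an ordered (predictor, outcome) pair and lag window `1..max_lag`,
#' builds the structures both model stages consume. Lags are calendar-day
#' differences, never observation-index differences: the predictor at lag
#' `l` is its value exactly `l` days before the outcome day, and is absent
#' (`NA`) if that day's diary is missing — absent values are never
#' zero-filled. The predictor may equal the outcome (auto-regression
#' design).
#'
#' @param panel a standardized panel (any tibble with `subject_id`, `date`
#'   and the two variables).
#' @param predictor,outcome variable names.
#' @param max_lag lag window upper bound (default 20 days).
#' @return a `lag_design` object: list with `wide` (one row per observed
#'   outcome day, lagged predictor columns `x_lag1..x_lagL`), `long` (rows
#'   `(subject, date, lag, y, x)` for observed predictor values only),
#'   `counts` (available pairs per lag), and the per-subject calendar-grid
#'   series used by the confirmatory stage.
#' @export
build_lag_design <- function(panel, predictor, outcome, max_lag = 20) {
  if (max_lag < 1) stop("max_lag must be >= 1", call. = FALSE)
  vars <- unique(c(predictor, outcome))
  for (v in vars) {
    if (!v %in% names(panel))
      stop("variable `", v, "` not in panel", call. = FALSE)
    if (all(is.na(panel[[v]])))
      stop("variable `", v, "` missing for all subjects", call. = FALSE)
  }
  ser <- panel_series(panel, vars)
  wide <- purrr::imap(ser, function(s, id) {
    x <- s$M[, predictor]
    y <- s$M[, outcome]
    Tn <- length(y)
    obs <- which(!is.na(y))
    if (!length(obs)) return(NULL)
    lagmat <- matrix(NA_real_, length(obs), max_lag)
    for (l in seq_len(max_lag)) {
      src <- obs - l
      keep <- src >= 1
      lagmat[keep, l] <- x[src[keep]]
    }
    colnames(lagmat) <- paste0("x_lag", seq_len(max_lag))
    dplyr::bind_cols(
      tibble::tibble(subject_id = id, date = s$dates[obs], y = y[obs]),
      tibble::as_tibble(lagmat))
  })
  wide <- dplyr::bind_rows(wide)
  long <- tidyr::pivot_longer(wide, cols = dplyr::starts_with("x_lag"),
                              names_to = "lag", names_prefix = "x_lag",
                              values_to = "x", values_drop_na = TRUE)
  long$lag <- as.integer(long$lag)
  counts <- dplyr::count(long, .data$lag, name = "n_pairs")
  structure(list(wide = wide, long = long, counts = counts, series = ser,
                 panel_vars = vars, predictor = predictor, outcome = outcome,
                 max_lag = as.integer(max_lag)),
            class = "lag_design")
}

#' @export
print.lag_design <- function(x, ...) {
  cat("<lag_design> ", x$predictor, " -> ", x$outcome,
      ", lags 1-", x$max_lag, "\n", sep = "")
  cat("  outcome rows:", nrow(x$wide), " stacked (t,l) pairs:",
      nrow(x$long), "\n")
  invisible(x)
}
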