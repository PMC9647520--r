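#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib esmlag, .registration = TRUE
#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

# diary item vocabulary ------------------------------------------------------

mood_items <- c("cheerful", "anxious", "relaxed", "irritable", "sad",
                "in_control", "stressed")
psychosis_items_all <- c("suspicious", "trouble_concentrating",
                         "preoccupied_by_thoughts", "others_dislike_me",
                         "confused", "others_influence_thoughts",
                         "unusual_sights_sounds")

#' Diary item names and composite definitions
#'
#' The daily diary holds four sleep fields (bed time, rise time, sleep
#' duration in hours, sleep quality on 1-5) and fourteen symptom items on a
#' 1-7 Likert scale. Six summary variables are derived: positive affect,
#' negative affect, cognitive symptoms, psychosis symptoms, and the secondary
#' paranoia and hallucinations scores.
#'
#' @return a named list: `items` (the 14 symptom items), `sleep` (sleep
#'   fields), `composites` (named list of constituent items per composite).
#' @export
diary_dictionary <- function() {
  list(
    items = c(mood_items, psychosis_items_all),
    sleep = c("time_into_bed", "time_out_of_bed", "sleep_duration",
              "sleep_quality"),
    composites = list(
      positive_affect = c("cheerful", "relaxed", "in_control"),
      negative_affect = c("anxious", "irritable", "sad", "stressed"),
      cognitive = c("trouble_concentrating", "confused"),
      psychosis = c("suspicious", "preoccupied_by_thoughts",
                    "others_dislike_me", "others_influence_thoughts",
                    "unusual_sights_sounds"),
      paranoia = c("suspicious", "others_dislike_me"),
      hallucinations = "unusual_sights_sounds"
    )
  )
}

item_range <- function(item) {
  if (item == "sleep_quality") return(c(1, 5))
  if (item == "sleep_duration") return(c(0, 16))
  if (item %in% c(mood_items, psychosis_items_all)) return(c(1, 7))
  NULL  # passthrough fields (bed / rise clock times)
}

value_ok <- function(item, value) {
  rng <- item_range(item)
  if (is.null(rng)) return(rep(TRUE, length(value)))
  ok <- !is.na(value) & value >= rng[1] & value <= rng[2]
  if (item != "sleep_duration") ok <- ok & value == round(value)
  else ok <- ok & abs(value / 0.25 - round(value / 0.25)) < 1e-8
  ok
}

#' Read a daily diary CSV
#'
#' Two dialects are supported. Long: columns `subject_id, date, item, value`
#' with one row per answered item. Wide: columns `subject_id, date` plus one
#' column per diary field. Values failing their range checks (sleep quality
#' 1-5, symptom items integer 1-7, sleep duration 0-16 h on a 0.25 h grid)
#' are rejected and counted in the cleaning report attached to the result
#' (see [cleaning_report()]); a wide row with any invalid value is dropped
#' whole. The file fails as a whole only if more than half of its rows are
#' invalid.
#'
#' @param path CSV file.
#' @param format `"wide"` or `"long"`.
#' @return a `diary_panel` tibble, one row per subject-date record.
#' @export
read_diary_csv <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  if (!nrow(raw)) stop("no records in ", path, call. = FALSE)
  if (!all(c("subject_id", "date") %in% names(raw)))
    stop("diary CSV must have subject_id and date columns", call. = FALSE)
  dates <- as.Date(raw$date)
  if (anyNA(dates)) stop("unparseable dates in ", path, call. = FALSE)
  raw$date <- dates
  raw$subject_id <- as.character(raw$subject_id)
  n_total <- nrow(raw)

  if (format == "long") {
    if (!all(c("item", "value") %in% names(raw)))
      stop("long format needs item and value columns", call. = FALSE)
    known <- c(diary_dictionary()$items, diary_dictionary()$sleep)
    bad_item <- !raw$item %in% known
    if (any(bad_item))
      stop("unknown item(s): ",
           paste(unique(raw$item[bad_item]), collapse = ", "), call. = FALSE)
    ok <- rep(TRUE, nrow(raw))
    for (it in unique(raw$item)) {
      sel <- raw$item == it
      v <- suppressWarnings(as.numeric(raw$value[sel]))
      ok[sel] <- value_ok(it, v)
    }
    n_rej <- sum(!ok)
    if (n_rej > nrow(raw) / 2)
      stop("more than half of the rows are invalid", call. = FALSE)
    raw <- raw[ok, , drop = FALSE]
    raw$value <- as.numeric(raw$value)
    panel <- tidyr::pivot_wider(raw, id_cols = c("subject_id", "date"),
                                names_from = "item", values_from = "value",
                                values_fn = function(x) x[[1]])
  } else {
    fields <- setdiff(names(raw), c("subject_id", "date"))
    known <- c(diary_dictionary()$items, diary_dictionary()$sleep)
    unknown <- setdiff(fields, known)
    if (length(unknown))
      stop("unknown column(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    ok <- rep(TRUE, nrow(raw))
    for (it in fields) {
      rng <- item_range(it)
      if (is.null(rng)) next
      v <- suppressWarnings(as.numeric(raw[[it]]))
      ok <- ok & value_ok(it, v)
      raw[[it]] <- v
    }
    n_rej <- sum(!ok)
    if (n_rej > nrow(raw) / 2)
      stop("more than half of the rows are invalid", call. = FALSE)
    panel <- raw[ok, , drop = FALSE]
  }
  if (!nrow(panel)) stop("no records after validation", call. = FALSE)
  panel <- dplyr::arrange(panel, .data$subject_id, .data$date)
  new_diary_panel(panel, report = list(rows_read = n_total,
                                       rows_rejected = n_rej))
}

new_diary_panel <- function(x, report = list()) {
  x <- tibble::as_tibble(x)
  class(x) <- c("diary_panel", class(x))
  attr(x, "report") <- report
  x
}

keep_panel_attrs <- function(out, panel, extra = list()) {
  rep0 <- c(attr(panel, "report") %||% list(), extra)
  new_diary_panel(out, report = rep0)
}

#' Cleaning report of a diary panel
#'
#' @param panel a `diary_panel`.
#' @return a list of counts accumulated by the cleaning steps (rows
#'   rejected, duplicates removed, subjects excluded with reasons, ...).
#' @export
cleaning_report <- function(panel) attr(panel, "report") %||% list()

#' Remove duplicate diary entries within a day
#'
#' Keeps the first entry per subject-date (earliest submission, i.e. first
#' occurrence in file order) and drops the rest; the number removed is added
#' to the cleaning report.
#'
#' @param panel a `diary_panel`.
#' @return the deduplicated panel.
#' @export
dedupe_daily <- function(panel) {
  key <- paste(panel$subject_id, panel$date)
  dup <- duplicated(key)
  out <- panel[!dup, , drop = FALSE]
  keep_panel_attrs(out, panel, list(duplicates_removed = sum(dup)))
}

#' Compute summary psychopathology composites
#'
#' Adds six columns: `positive_affect` (mean of cheerful, relaxed,
#' in_control), `negative_affect` (mean of anxious, irritable, sad,
#' stressed), `cognitive` (mean of trouble_concentrating, confused),
#' `psychosis` (mean of the five psychosis items), and the secondary scores
#' `paranoia` (mean of suspicious, others_dislike_me) and `hallucinations`
#' (the unusual_sights_sounds item). A record missing any constituent item
#' gets `NA` for that composite; nothing is imputed.
#'
#' @param panel a `diary_panel`.
#' @return the panel with composite columns appended.
#' @export
compute_composites <- function(panel) {
  defs <- diary_dictionary()$composites
  out <- panel
  for (nm in names(defs)) {
    cols <- defs[[nm]]
    missing_cols <- setdiff(cols, names(out))
    if (length(missing_cols)) {
      stop("cannot compute ", nm, ": item(s) ",
           paste(missing_cols, collapse = ", "), " absent", call. = FALSE)
    }
    out[[nm]] <- rowMeans(as.data.frame(out[cols]))  # NA if any item NA
  }
  keep_panel_attrs(out, panel)
}

#' Per-subject enrolment and response-rate summary
#'
#' @param panel a `diary_panel`.
#' @return a tibble with per-subject first/last dates, enrolled span in days,
#'   diaries submitted and response rate (submitted / span).
#' @export
panel_summary <- function(panel) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(panel), .data$subject_id),
    first_date = min(.data$date), last_date = max(.data$date),
    span_days = as.integer(.data$last_date - .data$first_date) + 1L,
    submitted = dplyr::n(),
    response_rate = .data$submitted / .data$span_days,
    .groups = "drop")
}

#' Exclude short-participation and invariant subjects
#'
#' Removes subjects enrolled for fewer than `min_days` calendar days
#' (first to last entry) and subjects whose responses show no variability:
#' pooled within-person standard deviation across all composite variables at
#' or below `variability_epsilon`.
#'
#' @param panel a `diary_panel` with composites computed.
#' @param min_days minimum enrolled span (default 30 days, i.e. one month).
#' @param variability_epsilon pooled-SD threshold (default 0: only exactly
#'   invariant response patterns are excluded).
#' @return the panel without excluded subjects; exclusions (subject, reason)
#'   are recorded in the cleaning report.
#' @export
exclude_subjects <- function(panel, min_days = 30, variability_epsilon = 0) {
  comps <- intersect(names(diary_dictionary()$composites), names(panel))
  if (!length(comps))
    stop("composites must be computed before exclusion", call. = FALSE)
  sm <- panel_summary(panel)
  excl <- tibble::tibble(subject_id = character(), reason = character())
  short <- sm$subject_id[sm$span_days < min_days]
  if (length(short))
    excl <- dplyr::bind_rows(excl, tibble::tibble(subject_id = short,
                                                  reason = "duration"))
  pooled_sd <- vapply(split(as.data.frame(panel[comps]), panel$subject_id),
                      function(d) stats::sd(unlist(d), na.rm = TRUE),
                      numeric(1))
  flat <- names(pooled_sd)[is.na(pooled_sd) | pooled_sd <= variability_epsilon]
  flat <- setdiff(flat, short)
  if (length(flat))
    excl <- dplyr::bind_rows(excl, tibble::tibble(subject_id = flat,
                                                  reason = "no variability"))
  out <- panel[!panel$subject_id %in% excl$subject_id, , drop = FALSE]
  if (!nrow(out)) stop("all subjects excluded", call. = FALSE)
  keep_panel_attrs(out, panel, list(subjects_excluded = excl))
}

#' Person-centred z-score standardization
#'
#' Standardizes each variable within subject: `z = (x - mean_s) / sd_s` over
#' that subject's observed days, with the usual n-1 denominator for the SD.
#' A subject-variable with zero variance is dropped (set `NA`) for that
#' subject, with a warning. The per-subject means and SDs used are attached
#' as attribute `"scaling"`.
#'
#' @param panel a `diary_panel` (or any tibble with `subject_id`, `date` and
#'   numeric variable columns).
#' @param vars variables to standardize; default: all composites plus
#'   `sleep_quality` and `sleep_duration` that are present, or all numeric
#'   columns for a generic panel.
#' @return a `standardized_panel` tibble.
#' @export
standardize_panel <- function(panel, vars = NULL) {
  if (is.null(vars)) {
    cand <- c(names(diary_dictionary()$composites), "sleep_quality",
              "sleep_duration")
    vars <- intersect(cand, names(panel))
    if (!length(vars)) {
      vars <- setdiff(names(panel)[vapply(panel, is.numeric, logical(1))],
                      c("day"))
    }
  }
  out <- tibble::as_tibble(panel)
  scaling <- list()
  for (v in vars) {
    st <- dplyr::summarise(dplyr::group_by(out, .data$subject_id),
                           mean = mean(.data[[v]], na.rm = TRUE),
                           sd = stats::sd(.data[[v]], na.rm = TRUE),
                           .groups = "drop")
    zero <- !is.na(st$sd) & st$sd == 0
    if (any(zero)) {
      warning("variable `", v, "` constant for subject(s) ",
              paste(st$subject_id[zero], collapse = ", "),
              "; dropped for them", call. = FALSE)
      st$sd[zero] <- NA_real_
    }
    i <- match(out$subject_id, st$subject_id)
    out[[v]] <- (out[[v]] - st$mean[i]) / st$sd[i]
    st$variable <- v
    scaling[[v]] <- st
  }
  out <- new_diary_panel(out, report = attr(panel, "report") %||% list())
  class(out) <- c("standardized_panel", class(out))
  attr(out, "scaling") <- dplyr::bind_rows(scaling)
  attr(out, "standardized_vars") <- vars
  out
}

#' Write a diary panel to CSV
#'
#' Inverse of [read_diary_csv()]; the round trip is lossless at the diary's
#' integer / 0.25-hour granularity.
#'
#' @param panel a `diary_panel`.
#' @param path output file.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_diary_csv <- function(panel, path, format = c("wide", "long")) {
  format <- match.arg(format)
  x <- tibble::as_tibble(panel)
  if (format == "long") {
    x <- tidyr::pivot_longer(x, cols = -c("subject_id", "date"),
                             names_to = "item", values_to = "value",
                             values_drop_na = TRUE)
  }
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Clean and standardize a diary panel end to end
#'
#' Applies the fixed cleaning order: duplicate removal, composite scoring,
#' subject exclusion, person-centred standardization. The pipeline is
#' idempotent: applying it twice equals applying it once.
#'
#' @param panel a `diary_panel` (e.g. from [read_diary_csv()]).
#' @inheritParams exclude_subjects
#' @return a `standardized_panel`.
#' @export
preprocess_diary <- function(panel, min_days = 30, variability_epsilon = 0) {
  panel |>
    dedupe_daily() |>
    compute_composites() |>
    exclude_subjects(min_days = min_days,
                     variability_epsilon = variability_epsilon) |>
    standardize_panel()
}
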