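# broom-style tidiers

#' Tidy a smooth lag fit
#'
#' @param x a `smooth_lag_fit`.
#' @param ... unused.
#' @return a tibble with one row per integer lag.
#' @export
tidy.smooth_lag_fit <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "smooth_lag_fit")
  out
}

#' @rdname tidy.smooth_lag_fit
#' @export
glance.smooth_lag_fit <- function(x, ...) {
  tibble::tibble(k = attr(x, "k"),
                 sp = attr(x, "sp")[1],
                 edf = attr(x, "edf"),
                 gcv = attr(x, "gcv"),
                 subject_var = attr(x, "subject_var"),
                 nobs = attr(x, "n"))
}

#' Tidy a confirmatory lag model fit
#'
#' @param x a `lag_model_fit` or `final_lag_model`.
#' @param ... unused.
#' @return one row per retained coefficient (`path`, `lag`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @export
tidy.lag_model_fit <- function(x, ...) x$coefficients

#' @rdname tidy.lag_model_fit
#' @export
glance.lag_model_fit <- function(x, ...) {
  tibble::tibble(
    predictor = x$predictor, outcome = x$outcome,
    lags = format_lag_runs(c(x$retained_cross, x$retained_auto)),
    summed_beta = sum(x$coefficients$estimate),
    logLik = x$loglik, BIC = x$BIC, n_params = x$n_params,
    nobs = x$n_obs, n_subjects = x$n_subjects)
}

#' @rdname tidy.lag_model_fit
#' @export
tidy.final_lag_model <- function(x, ...) tidy(x$fit)

#' @rdname tidy.lag_model_fit
#' @export
glance.final_lag_model <- function(x, ...) {
  dplyr::bind_cols(glance(x$fit),
                   tibble::tibble(cycles = x$n_cycles,
                                  converged = x$converged,
                                  oscillation = x$oscillation))
}

#' Tidy a mediation result
#'
#' @param x a `mediation_result`.
#' @param ... unused.
#' @return a one-row tibble with the triple, per-path significant lags in
#'   run notation, summed total/direct/indirect effects, BICs and verdict.
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    predictor = x$predictor, mediator = x$mediator, outcome = x$outcome,
    lags_a = format_lag_runs(x$lags$a),
    lags_b = format_lag_runs(x$lags$b),
    lags_direct = format_lag_runs(x$lags$direct),
    total = x$effects[["total"]], direct = x$effects[["direct"]],
    indirect = x$effects[["indirect"]],
    bic_unmediated = x$bic[["unmediated"]],
    bic_mediated = x$bic[["mediated"]],
    verdict = x$verdict,
    preferred = if (!is.null(x$comparison)) x$comparison$preferred
                else NA_character_)
}

#' @rdname tidy.mediation_result
#' @export
glance.mediation_result <- function(x, ...) tidy(x)

#' Path-diagram text for a mediation result
#'
#' Writes the a, b, c (total) and c' (direct) paths with their significant
#' lag sets and summed coefficients.
#'
#' @param x a `mediation_result`.
#' @return a character vector, one line per path, invisibly; also printed.
#' @export
mediation_paths <- function(x) {
  stopifnot(inherits(x, "mediation_result"))
  a_eff <- sum(x$path_a$fit$coefficients$estimate)
  lines <- c(
    sprintf("a  (%s -> %s): lags %s, summed beta %.3f", x$predictor,
            x$mediator, format_lag_runs(x$lags$a), a_eff),
    sprintf("b  (%s -> %s | %s): lags %s", x$mediator, x$outcome,
            x$predictor, format_lag_runs(x$lags$b)),
    sprintf("c  (%s -> %s, total): lags %s, summed beta %.3f", x$predictor,
            x$outcome, format_lag_runs(x$lags$total), x$effects[["total"]]),
    sprintf("c' (%s -> %s | %s, direct): lags %s, summed beta %.3f",
            x$predictor, x$outcome, x$mediator,
            format_lag_runs(x$lags$direct), x$effects[["direct"]]))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
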