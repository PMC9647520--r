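# lag-space mediation: Baron-Kenny steps with the joint significance test,
# total/direct/indirect summed effects and BIC model comparison

#' Fit mediation path a (predictor to mediator)
#'
#' First Baron-Kenny step: the putative mediator is regressed on the
#' predictor with the full two-stage procedure. An empty retained lag set
#' means the intermediate variable cannot act as a mediator and
#' short-circuits the mediation with verdict "no mediation".
#'
#' @inheritParams iterate_two_stage
#' @param mediator mediator variable name.
#' @return a `final_lag_model` for predictor -> mediator.
#' @export
fit_path_a <- function(panel, predictor, mediator, max_lag = 20,
                       alpha = 0.05, k = 19, engine = "auto") {
  if (identical(predictor, mediator))
    stop("predictor and mediator must differ", call. = FALSE)
  iterate_two_stage(panel, predictor, mediator, max_lag = max_lag,
                    alpha = alpha, k = k, engine = engine)
}

# joint three-series confirmatory fit: y on predictor lags (direct path) and
# mediator lags (path b), with nuisance dynamics for predictor (AR 1) and
# mediator (AR 1 + the path-a lags from the predictor)
fit_joint_outcome <- function(panel, predictor, mediator, outcome,
                              direct_lags, b_lags, a_lags, alpha = 0.05,
                              prune = TRUE, start_direct = NULL,
                              start_b = NULL, start_a = NULL) {
  vars <- c(predictor, mediator, outcome)
  ser <- panel_series(panel, vars)
  pieces <- list(
    tibble::tibble(target = predictor, source = predictor, lag = 1L,
                   role = "nuisance", start = ar_start(ser, predictor)),
    tibble::tibble(target = mediator, source = mediator, lag = 1L,
                   role = "nuisance", start = ar_start(ser, mediator)))
  if (length(a_lags))
    pieces <- c(pieces, list(
      tibble::tibble(target = mediator, source = predictor,
                     lag = as.integer(a_lags), role = "nuisance",
                     start = start_a %||% 0)))
  if (length(direct_lags))
    pieces <- c(pieces, list(
      tibble::tibble(target = outcome, source = predictor,
                     lag = as.integer(direct_lags), role = "path_direct",
                     start = start_direct %||% 0)))
  if (length(b_lags))
    pieces <- c(pieces, list(
      tibble::tibble(target = outcome, source = mediator,
                     lag = as.integer(b_lags), role = "path_b",
                     start = start_b %||% 0)))
  eqs <- dplyr::bind_rows(pieces)

  # pairwise-moment warm starts for the outcome and mediator equations
  yterms <- eqs[eqs$target == outcome, c("source", "lag")]
  if (nrow(yterms)) {
    ms <- moment_start(ser, outcome, yterms)
    eqs$start[eqs$target == outcome] <- ms$coef
  }
  mterms <- eqs[eqs$target == mediator, c("source", "lag")]
  if (nrow(mterms)) {
    mm <- moment_start(ser, mediator, mterms)
    eqs$start[eqs$target == mediator] <- mm$coef
  }
  sig_start <- c(1, if (nrow(mterms)) mm$sigma else 1,
                 if (nrow(yterms)) ms$sigma else 1)

  eliminated <- list()
  repeat {
    fit <- ss_fit(ser, vars, eqs, outcome, sigma_start = sig_start,
                  se = if (any(eqs$role != "nuisance")) "diag" else "none")
    sig_start <- fit$sigma
    path <- fit$eqs[fit$eqs$role != "nuisance", ]
    if (!prune || !nrow(path)) break
    pv <- path$p.value
    pv[is.na(pv)] <- 1
    if (all(pv < alpha)) break
    worst <- which.max(pv)
    eliminated[[length(eliminated) + 1]] <-
      list(source = path$source[worst], lag = path$lag[worst],
           p.value = pv[worst])
    drop_row <- which(eqs$role != "nuisance")[worst]
    eqs <- fit$eqs[-drop_row, ]
    eqs$start <- eqs$estimate
    eqs <- eqs[, c("target", "source", "lag", "role", "start")]
  }
  # final model: full observed information; resume pruning if a coefficient
  # no longer clears alpha under the exact SEs
  repeat {
    if (!any(fit$eqs$role != "nuisance")) break
    eqs_f <- fit$eqs[, c("target", "source", "lag", "role", "start")]
    eqs_f$start <- fit$eqs$estimate
    fit <- ss_fit(ser, vars, eqs_f, outcome, sigma_start = fit$sigma,
                  se = "full")
    if (!prune) break
    path <- fit$eqs[fit$eqs$role != "nuisance", ]
    pv <- path$p.value
    pv[is.na(pv)] <- 1
    if (!length(pv) || all(pv < alpha)) break
    worst <- which.max(pv)
    eliminated[[length(eliminated) + 1]] <-
      list(source = path$source[worst], lag = path$lag[worst],
           p.value = pv[worst])
    drop_row <- which(fit$eqs$role != "nuisance")[worst]
    fit$eqs <- fit$eqs[-drop_row, ]
    fit$eqs$start <- fit$eqs$estimate
  }
  pp <- fit$eqs[fit$eqs$role != "nuisance", , drop = FALSE]
  n_subj <- length(ser)
  n_params <- nrow(pp) + 1L + n_subj
  bic <- -2 * fit$loglik_y + n_params * log(max(fit$n_y, 1))
  list(coefficients = tibble::tibble(
         path = sub("path_", "", pp$role), predictor = pp$source,
         lag = pp$lag, estimate = pp$estimate,
         std.error = pp$std.error, statistic = pp$statistic,
         p.value = pp$p.value),
       nuisance = fit$eqs[fit$eqs$role == "nuisance", , drop = FALSE],
       loglik = fit$loglik_y, n_obs = fit$n_y, n_params = n_params,
       BIC = bic, eliminated = eliminated, convergence = fit$convergence)
}

#' Lag-space mediation analysis
#'
#' Follows the Baron-Kenny approach with the joint significance test, in lag
#' space. Steps: (1) path a, predictor -> mediator, two-stage model; an
#' empty retained set short-circuits with verdict "no mediation"; (2) the
#' total-effect model predictor -> outcome; (3) screening of the mediator's
#' own lags on the outcome (path b candidates; `rescreen = FALSE` reuses the
#' total model's lag sets instead); (4) the mediated model, in which the
#' predictor's and the mediator's retained lag sets enter the outcome
#' equation together, giving the direct effect (predictor -> outcome given
#' the mediator) and path b; (5) the indirect effect as total minus direct
#' (summed-coefficient difference method, exact by construction).
#'
#' Mediation is claimed only when paths a and b are both significant (their
#' final retained sets are non-empty). The verdict is "full" when the direct
#' path's retained set is empty, "partial" when the direct effect stays
#' significant but is smaller in magnitude than the total effect, and
#' "none" otherwise. Model fit of the unmediated and mediated outcome models
#' is compared by BIC (lower is closer). Unless `oppositional = FALSE`, the
#' whole procedure is repeated with predictor and mediator roles exchanged,
#' and the comparison reports which model offers the more parsimonious
#' account: presence of an indirect pathway first, lower mediated-model BIC
#' as the tie-break (ties within 1e-6 are inconclusive).
#'
#' @inheritParams iterate_two_stage
#' @param mediator mediator variable name.
#' @param rescreen re-screen the mediator's lags on the outcome for path b
#'   (default) rather than reusing lag sets from the unmediated analyses.
#' @param oppositional also fit the role-swapped model.
#' @param .cache internal memoisation environment so that pair models shared
#'   between the forward and oppositional analyses are fitted once.
#' @return a `mediation_result`.
#' @export
mediation_analysis <- function(panel, predictor, mediator, outcome,
                               max_lag = 20, alpha = 0.05, k = 19,
                               rescreen = TRUE, oppositional = TRUE,
                               engine = "auto", .cache = NULL) {
  if (anyDuplicated(c(predictor, mediator, outcome)))
    stop("predictor, mediator and outcome must be distinct variables",
         call. = FALSE)
  if (is.null(.cache)) .cache <- new.env(parent = emptyenv())
  its <- function(p, o) {
    key <- paste0(p, "->", o)
    if (is.null(.cache[[key]])) {
      .cache[[key]] <- iterate_two_stage(panel, p, o, max_lag = max_lag,
                                         alpha = alpha, k = k,
                                         engine = engine)
    }
    .cache[[key]]
  }
  path_a <- its(predictor, mediator)
  a_lags <- retained_lags(path_a)
  total <- its(predictor, outcome)
  total_lags <- retained_lags(total)
  total_effect <- as.numeric(summed_effect(total))

  joint <- NULL
  b_screen <- NULL
  direct_effect <- total_effect
  direct_lags <- integer(0)
  b_lags_final <- integer(0)
  if (length(a_lags)) {
    b_cand <- if (rescreen) {
      b_screen <- its(mediator, outcome)
      retained_lags(b_screen)
    } else total_lags
    if (length(b_cand)) {
      joint <- fit_joint_outcome(
        panel, predictor, mediator, outcome,
        direct_lags = total_lags, b_lags = b_cand, a_lags = a_lags,
        alpha = alpha,
        start_direct = total$fit$coefficients$estimate,
        start_b = if (!is.null(b_screen)) b_screen$fit$coefficients$estimate,
        start_a = path_a$fit$coefficients$estimate)
      cc <- joint$coefficients
      direct_lags <- sort(cc$lag[cc$path == "direct"])
      b_lags_final <- sort(cc$lag[cc$path == "b"])
      direct_effect <- sum(cc$estimate[cc$path == "direct"])
    } else {
      direct_effect <- total_effect
    }
  }
  indirect_effect <- total_effect - direct_effect

  a_sig <- length(a_lags) > 0
  b_sig <- length(b_lags_final) > 0
  verdict <- if (!a_sig || !b_sig) {
    "no mediation"
  } else if (!length(direct_lags)) {
    "full"
  } else if (abs(direct_effect) < abs(total_effect)) {
    "partial"
  } else {
    "none"
  }
  has_indirect <- a_sig && b_sig

  res <- list(predictor = predictor, mediator = mediator, outcome = outcome,
              path_a = path_a, total = total, b_screen = b_screen,
              joint = joint,
              lags = list(a = a_lags, total = total_lags,
                          direct = direct_lags, b = b_lags_final),
              effects = c(total = total_effect, direct = direct_effect,
                          indirect = indirect_effect),
              bic = c(unmediated = total$fit$BIC,
                      mediated = if (!is.null(joint)) joint$BIC else NA_real_),
              verdict = verdict, has_indirect = has_indirect,
              alpha = alpha)
  class(res) <- "mediation_result"

  if (oppositional) {
    opp <- mediation_analysis(panel, predictor = mediator,
                              mediator = predictor, outcome = outcome,
                              max_lag = max_lag, alpha = alpha, k = k,
                              rescreen = rescreen, oppositional = FALSE,
                              engine = engine, .cache = .cache)
    res$oppositional <- opp
    res$comparison <- compare_mediation(res, opp)
  }
  res
}

#' Oppositional mediation model
#'
#' Convenience wrapper running [mediation_analysis()] with predictor and
#' mediator roles exchanged.
#'
#' @inheritParams mediation_analysis
#' @return a `mediation_result`.
#' @export
fit_oppositional_model <- function(panel, predictor, mediator, outcome,
                                   max_lag = 20, alpha = 0.05, k = 19,
                                   rescreen = TRUE, engine = "auto") {
  mediation_analysis(panel, predictor = mediator, mediator = predictor,
                     outcome = outcome, max_lag = max_lag, alpha = alpha,
                     k = k, rescreen = rescreen, oppositional = FALSE,
                     engine = engine)
}

# adjudicate forward vs oppositional model
compare_mediation <- function(fwd, opp, tol = 1e-6) {
  f_ind <- isTRUE(fwd$has_indirect)
  o_ind <- isTRUE(opp$has_indirect)
  if (f_ind && !o_ind) {
    list(preferred = "forward",
         reason = "only the forward model shows an indirect pathway")
  } else if (!f_ind && o_ind) {
    list(preferred = "oppositional",
         reason = "only the oppositional model shows an indirect pathway")
  } else if (!f_ind && !o_ind) {
    list(preferred = "inconclusive",
         reason = "neither model shows an indirect pathway")
  } else {
    fb <- fwd$bic[["mediated"]]
    ob <- opp$bic[["mediated"]]
    if (is.na(fb) || is.na(ob) || abs(fb - ob) <= tol) {
      list(preferred = "inconclusive",
           reason = "both models show an indirect pathway with equivalent fit")
    } else if (fb < ob) {
      list(preferred = "forward", reason = "lower BIC for the forward model")
    } else {
      list(preferred = "oppositional",
           reason = "lower BIC for the oppositional model")
    }
  }
}

retained_lags <- function(x) {
  if (inherits(x, "final_lag_model")) x <- x$fit
  if (x$predictor == x$outcome) x$retained_auto else x$retained_cross
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation: ", x$predictor, " -> ", x$mediator, " -> ", x$outcome,
      "\n", sep = "")
  cat("  path a lags: ", format_lag_runs(x$lags$a),
      " | path b lags: ", format_lag_runs(x$lags$b),
      " | direct lags: ", format_lag_runs(x$lags$direct), "\n", sep = "")
  e <- x$effects
  cat(sprintf("  total = %.3f, direct = %.3f, indirect = %.3f\n",
              e["total"], e["direct"], e["indirect"]))
  cat(sprintf("  BIC unmediated = %.1f, mediated = %.1f\n",
              x$bic["unmediated"], x$bic["mediated"]))
  cat("  verdict:", x$verdict, "\n")
  if (!is.null(x$comparison))
    cat("  vs oppositional:", x$comparison$preferred, "-",
        x$comparison$reason, "\n")
  invisible(x)
}
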