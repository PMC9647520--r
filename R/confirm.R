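# confirmatory stage: discrete-lag dynamic model fitted by Gaussian maximum
# likelihood in a state-space form whose state carries the lagged values;
# missing days are marginalized by the Kalman filter.

# ---- generic state-space fit ------------------------------------------------

# series_list: per-subject list(M = T x k matrix, cols named)
# eqs: tibble(target, source, lag, role, start); roles "path_*" are subject
#      to Wald pruning, "nuisance" terms are kept.
ss_fit <- function(series_list, vars, eqs, outcome,
                   intercept = TRUE, prior_var = NULL, sigma_start = NULL,
                   se = c("full", "path", "diag", "none"), control = list()) {
  se <- match.arg(se)
  k <- length(vars)
  mats <- lapply(series_list, function(s) {
    M <- s$M[, vars, drop = FALSE]
    storage.mode(M) <- "double"
    M
  })
  depth <- vapply(vars, function(v) {
    max(1L, eqs$lag[eqs$source == v], na.rm = TRUE)
  }, integer(1))
  m0 <- max(1L, eqs$lag)
  if (is.null(prior_var)) {
    prior_var <- vapply(vars, function(v) {
      x <- unlist(lapply(mats, function(M) M[, v]))
      v0 <- stats::var(x, na.rm = TRUE)
      if (!is.finite(v0) || v0 <= 0) 1 else v0
    }, numeric(1))
  }
  if (is.null(sigma_start)) sigma_start <- sqrt(prior_var)
  eqm <- cbind(match(eqs$target, vars), match(eqs$source, vars), eqs$lag)
  storage.mode(eqm) <- "integer"
  ic <- if (intercept) match(outcome, vars) else 0L
  oc <- match(outcome, vars)
  np <- nrow(eqs)

  negll <- function(theta) {
    out <- ss_loglik_cpp(mats, eqm, theta[seq_len(np)],
                         exp(theta[np + seq_len(k)]), depth, m0, ic, oc,
                         prior_var)
    ll <- out$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  theta0 <- c(eqs$start, log(pmax(sigma_start, 1e-4)))
  # scale parameters to roughly unit curvature (information ~ n per
  # coefficient) so BFGS takes well-sized first steps
  n_est <- sum(vapply(mats, function(M) sum(!is.na(M)), numeric(1)))
  ctrl <- utils::modifyList(
    list(maxit = 300, reltol = 1e-10,
         parscale = rep(1 / sqrt(max(n_est, 100)), length(theta0))),
    control)
  opt <- stats::optim(theta0, negll, method = "BFGS", control = ctrl)
  if (!is.finite(opt$value) || opt$convergence > 1) {
    for (r in 1:2) {  # perturbed restarts on failure
      th <- theta0 + stats::rnorm(length(theta0), 0, 0.05 * r)
      o2 <- stats::optim(th, negll, method = "BFGS", control = ctrl)
      if (is.finite(o2$value) && o2$value < opt$value) opt <- o2
    }
  }
  theta <- opt$par
  det <- ss_loglik_cpp(mats, eqm, theta[seq_len(np)],
                       exp(theta[np + seq_len(k)]), depth, m0, ic, oc,
                       prior_var)
  vc <- matrix(NA_real_, np, np)
  idx <- if (se == "full") seq_along(theta)
         else if (se %in% c("path", "diag")) which(eqs$role != "nuisance")
         else integer(0)
  if (length(idx) && np > 0) {
    H <- if (se == "diag") {
      # diagonal-only observed information: cheap screening precision for
      # pruning decisions (final SEs always come from the full information)
      f0 <- opt$value
      d <- vapply(idx, function(i) {
        hi <- max(1e-4, 1e-4 * abs(theta[i]))
        ei <- replace(numeric(length(theta)), i, hi)
        (negll(theta + ei) - 2 * f0 + negll(theta - ei)) / hi^2
      }, numeric(1))
      diag(d, length(idx))
    } else num_hessian_sub(negll, theta, idx)
    vc_all <- try(solve(H), silent = TRUE)
    if (inherits(vc_all, "try-error") || any(!is.finite(diag(vc_all))) ||
        any(diag(vc_all) < 0)) {
      vc_all <- MASS::ginv(H)
      dg <- diag(vc_all)
      dg[dg < 0] <- NA_real_
      diag(vc_all) <- dg
    }
    keep <- idx[idx <= np]
    vc[keep, keep] <- vc_all[match(keep, idx), match(keep, idx)]
  }
  eqs$estimate <- theta[seq_len(np)]
  eqs$std.error <- sqrt(diag(vc))
  eqs$statistic <- eqs$estimate / eqs$std.error
  eqs$p.value <- 2 * stats::pnorm(-abs(eqs$statistic))
  list(eqs = eqs, sigma = stats::setNames(exp(theta[np + seq_len(k)]), vars),
       loglik = det$loglik, loglik_y = det$loglik_y, n_y = det$n_y,
       n_obs = det$n_obs,
       mu = stats::setNames(det$mu, names(series_list)),
       vcov = vc, convergence = opt$convergence, m0 = m0, depth = depth)
}

# central-difference Hessian of f at x restricted to coordinates idx
num_hessian_sub <- function(f, x, idx = seq_along(x), h = NULL) {
  n <- length(idx)
  if (is.null(h)) h <- pmax(1e-4, 1e-4 * abs(x[idx]))
  H <- matrix(0, n, n)
  f0 <- f(x)
  nn <- length(x)
  for (a in seq_len(n)) {
    i <- idx[a]
    ei <- replace(numeric(nn), i, h[a])
    H[a, a] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[a]^2
    if (a < n) for (b in (a + 1):n) {
      j <- idx[b]
      ej <- replace(numeric(nn), j, h[b])
      H[a, b] <- H[b, a] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[a] * h[b])
    }
  }
  (H + t(H)) / 2
}

# complete-case within-subject OLS start values (Frisch-Waugh demeaning,
# equivalent to OLS with subject dummies)
ols_start <- function(series_list, predictor, outcome, cross, auto) {
  rows <- list()
  for (s in series_list) {
    x <- s$M[, predictor]
    y <- s$M[, outcome]
    Tn <- length(y)
    m0 <- max(1L, cross, auto)
    t_idx <- seq.int(m0 + 1L, Tn)
    Xl <- sapply(cross, function(l) x[t_idx - l])
    Yl <- sapply(auto, function(m) y[t_idx - m])
    Z <- cbind(if (length(cross)) Xl, if (length(auto)) Yl)
    yy <- y[t_idx]
    keep <- stats::complete.cases(cbind(yy, Z))
    if (sum(keep) < length(cross) + length(auto) + 2) next
    Z <- Z[keep, , drop = FALSE]
    yy <- yy[keep]
    rows[[length(rows) + 1]] <-
      cbind(yy - mean(yy), sweep(Z, 2, colMeans(Z)))
  }
  if (!length(rows)) {
    return(list(coef = numeric(length(cross) + length(auto)), sigma = 1,
                n = 0))
  }
  M <- do.call(rbind, rows)
  yy <- M[, 1]
  Z <- M[, -1, drop = FALSE]
  fit <- stats::lm.fit(Z, yy)
  list(coef = unname(fit$coefficients),
       sigma = sqrt(mean(fit$residuals^2)), n = length(yy))
}

# warm starts from pairwise-complete within-person moments: each series is
# demeaned by its subject mean over observed days, cross-products accumulate
# over days where both lagged terms are observed
moment_start <- function(series_list, outcome, terms) {
  nt <- nrow(terms)
  S <- matrix(0, nt, nt)
  sy <- numeric(nt)
  for (s in series_list) {
    M <- s$M
    Tn <- nrow(M)
    cm <- colMeans(M, na.rm = TRUE)
    cm[is.na(cm)] <- 0
    Md <- sweep(M, 2, cm)
    y <- Md[, outcome]
    Z <- matrix(NA_real_, Tn, nt)
    for (j in seq_len(nt)) {
      l <- terms$lag[j]
      Z[(l + 1):Tn, j] <- Md[seq_len(Tn - l), terms$source[j]]
    }
    for (j in seq_len(nt)) {
      zy <- Z[, j] * y
      sy[j] <- sy[j] + sum(zy, na.rm = TRUE)
      for (j2 in j:nt) {
        v <- sum(Z[, j] * Z[, j2], na.rm = TRUE)
        S[j, j2] <- S[j, j2] + v
        S[j2, j] <- S[j, j2]
      }
    }
  }
  cf <- try(solve(S + 1e-8 * diag(nt) * max(diag(S)), sy), silent = TRUE)
  if (inherits(cf, "try-error") || any(!is.finite(cf))) cf <- rep(0, nt)
  cf <- pmin(pmax(cf, -0.95), 0.95)
  # crude residual sd from total variance minus explained (floored)
  vy <- stats::var(unlist(lapply(series_list,
                                 function(s) s$M[, outcome])), na.rm = TRUE)
  sig2 <- max(vy - sum(cf * sy) / max(sum(vapply(series_list,
            function(s) sum(!is.na(s$M[, outcome])), numeric(1))), 1), 0.1 * vy)
  list(coef = as.numeric(cf), sigma = sqrt(sig2))
}

ar_start <- function(series_list, var, p = 1L) {
  num <- den <- 0
  for (s in series_list) {
    x <- s$M[, var]
    x <- x - mean(x, na.rm = TRUE)
    x0 <- x[-1]; x1 <- x[-length(x)]
    ok <- !is.na(x0) & !is.na(x1)
    num <- num + sum(x0[ok] * x1[ok])
    den <- den + sum(x1[ok]^2)
  }
  if (den <= 0) 0 else num / den
}

# ---- confirmatory lag model -------------------------------------------------

#' Confirmatory fit at a discrete candidate lag set
#'
#' Fits \deqn{y_t = \sum_{l \in cross} \beta_l x_{t-l} +
#'   \sum_{m \in auto} \phi_m y_{t-m} + \mu_{subject} + \epsilon_t}
#' by Gaussian maximum likelihood in a state-space formulation whose state
#' carries the lagged values of both series; days with a missing diary are
#' marginalized by the Kalman filter rather than dropped or imputed, and the
#' predictor series is given a nuisance AR(`x_ar`) model so that its missing
#' values carry the right uncertainty. Per-subject intercepts on the outcome
#' are concentrated out of the likelihood exactly. After the initial fit,
#' backward elimination iteratively drops the least significant path
#' coefficient with `p >= alpha` and refits, until every retained
#' coefficient has `p < alpha`.
#'
#' The reported log-likelihood is the outcome equation's (conditional)
#' Gaussian log-likelihood, and `BIC = -2 loglik + n_params log(n_obs)` with
#' `n_params` counting the retained path coefficients, the innovation SD and
#' the subject intercepts.
#'
#' @param design a [build_lag_design()] result.
#' @param candidate_lags integer candidate cross-lags (auto-lags when the
#'   design's predictor equals its outcome).
#' @param auto_lags integer candidate auto-lags of the outcome (optional).
#' @param alpha Wald pruning level (default 0.05).
#' @param prune run backward elimination (default `TRUE`).
#' @param x_ar nuisance autoregressive order for the predictor series.
#' @param se compute Wald standard errors (numerical observed information).
#' @return a `lag_model_fit` object.
#' @export
fit_lag_model <- function(design, candidate_lags, auto_lags = integer(0),
                          alpha = 0.05, prune = TRUE, x_ar = 1L, se = TRUE) {
  stopifnot(inherits(design, "lag_design"))
  predictor <- design$predictor
  outcome <- design$outcome
  selfreg <- predictor == outcome
  cross <- sort(unique(as.integer(candidate_lags)))
  auto <- sort(unique(as.integer(auto_lags)))
  if (selfreg) {
    auto <- sort(unique(c(cross, auto)))
    cross <- integer(0)
  }
  if (any(c(cross, auto) < 1) || any(c(cross, auto) > design$max_lag))
    stop("candidate lags must lie in 1..max_lag", call. = FALSE)
  vars <- if (selfreg) outcome else c(predictor, outcome)
  ser <- design$series

  build_eqs <- function(cross, auto, start_path = NULL, start_nuis = NULL) {
    pieces <- list()
    if (!selfreg && x_ar >= 1) {
      pieces$nx <- tibble::tibble(target = predictor, source = predictor,
                                  lag = seq_len(x_ar), role = "nuisance",
                                  start = 0)
    }
    if (length(cross)) {
      pieces$cr <- tibble::tibble(target = outcome, source = predictor,
                                  lag = cross, role = "path_cross", start = 0)
    }
    if (length(auto)) {
      pieces$au <- tibble::tibble(target = outcome, source = outcome,
                                  lag = auto, role = "path_auto", start = 0)
    }
    eqs <- dplyr::bind_rows(pieces)
    if (!nrow(eqs)) {
      eqs <- tibble::tibble(target = character(), source = character(),
                            lag = integer(), role = character(),
                            start = numeric())
    }
    if (!is.null(start_path)) {
      eqs$start[eqs$role != "nuisance"] <- start_path
    }
    if (!is.null(start_nuis) && any(eqs$role == "nuisance")) {
      eqs$start[eqs$role == "nuisance"] <- start_nuis
    }
    eqs
  }

  has_cand <- length(cross) + length(auto) > 0
  st <- if (has_cand) ols_start(ser, predictor, outcome, cross, auto)
        else list(coef = NULL, sigma = 1)
  gx <- if (!selfreg && x_ar >= 1) ar_start(ser, predictor) else NULL
  sig_start <- if (selfreg) st$sigma else c(1, st$sigma)
  eqs <- build_eqs(cross, auto, start_path = st$coef, start_nuis = gx)

  eliminated <- list()
  repeat {
    if (!any(eqs$role != "nuisance")) {
      # null model: nuisance dynamics only (empty retained set)
      eqs <- build_eqs(integer(0), integer(0), start_nuis = gx)
      fit <- ss_fit(ser, vars, eqs, outcome, sigma_start = sig_start,
                    se = "none")
      break
    }
    # pruning decisions use the cheaper path-block observed information;
    # the final model below reports SEs from the full observed information
    fit <- ss_fit(ser, vars, eqs, outcome, sigma_start = sig_start,
                  se = if (prune && se) "path" else if (se) "full"
                       else "none")
    path <- fit$eqs[fit$eqs$role != "nuisance", ]
    if (!prune || !se || !nrow(path)) break
    pv <- path$p.value
    pv[is.na(pv)] <- 1
    worst <- which.max(pv)
    if (pv[worst] < alpha) break
    eliminated[[length(eliminated) + 1]] <-
      list(source = path$source[worst], lag = path$lag[worst],
           p.value = pv[worst])
    keep <- fit$eqs
    drop_row <- which(keep$role != "nuisance")[worst]
    keep <- keep[-drop_row, ]
    cross <- keep$lag[keep$role == "path_cross"]
    auto <- keep$lag[keep$role == "path_auto"]
    eqs <- build_eqs(cross, auto,
                     start_path = keep$estimate[keep$role != "nuisance"],
                     start_nuis = keep$estimate[keep$role == "nuisance"])
    if (!nrow(eqs) || !any(eqs$role != "nuisance")) next  # all pruned
  }
  # final model under the full observed information; pruning resumes if a
  # coefficient no longer clears alpha under the exact SEs
  while (prune && se && any(fit$eqs$role != "nuisance")) {
    eqs_f <- fit$eqs[, c("target", "source", "lag", "role", "start")]
    eqs_f$start <- fit$eqs$estimate
    fit <- ss_fit(ser, vars, eqs_f, outcome, sigma_start = fit$sigma,
                  se = "full")
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
    if (!any(fit$eqs$role != "nuisance")) {
      eqs0 <- build_eqs(integer(0), integer(0), start_nuis = gx)
      fit <- ss_fit(ser, vars, eqs0, outcome, sigma_start = fit$sigma,
                    se = "none")
      break
    }
  }

  pp <- fit$eqs[fit$eqs$role != "nuisance", , drop = FALSE]
  coefs <- tibble::tibble(
    path = sub("path_", "", pp$role),
    predictor = pp$source, lag = pp$lag,
    estimate = pp$estimate, std.error = pp$std.error,
    statistic = pp$statistic, p.value = pp$p.value)
  n_subj <- length(ser)
  n_params <- nrow(coefs) + 1L + n_subj
  bic <- -2 * fit$loglik_y + n_params * log(max(fit$n_y, 1))
  structure(list(
    coefficients = coefs,
    nuisance = fit$eqs[fit$eqs$role == "nuisance", , drop = FALSE],
    retained_cross = sort(coefs$lag[coefs$path == "cross"]),
    retained_auto = sort(coefs$lag[coefs$path == "auto"]),
    candidate_cross = sort(unique(as.integer(candidate_lags))),
    candidate_auto = sort(unique(as.integer(auto_lags))),
    loglik = fit$loglik_y, n_obs = fit$n_y, n_subjects = n_subj,
    n_params = n_params, BIC = bic, sigma = fit$sigma, mu = fit$mu,
    eliminated = eliminated, convergence = fit$convergence,
    alpha = alpha, predictor = predictor, outcome = outcome,
    max_lag = design$max_lag), class = "lag_model_fit")
}

#' Summed effect size over retained lags
#'
#' The combined effect size of all significant lags between two variables:
#' the exact sum of the retained standardized coefficients on the requested
#' path. Zero (flagged n.s.) for an empty retained set.
#'
#' @param fit a `lag_model_fit` or `final_lag_model`.
#' @param path `"cross"` or `"auto"`.
#' @return a single number with attribute `"n.s."` set to `TRUE` when the
#'   retained set is empty.
#' @export
summed_effect <- function(fit, path = c("cross", "auto")) {
  path <- match.arg(path)
  if (inherits(fit, "final_lag_model")) fit <- fit$fit
  stopifnot(inherits(fit, "lag_model_fit"))
  cc <- fit$coefficients
  if (fit$predictor == fit$outcome && path == "cross") path <- "auto"
  est <- cc$estimate[cc$path == path]
  out <- sum(est)
  attr(out, "n.s.") <- length(est) == 0
  out
}

#' @export
print.lag_model_fit <- function(x, ...) {
  cat("Confirmatory lag model: ", x$predictor, " -> ", x$outcome, "\n",
      sep = "")
  cat("  retained lags: ", format_lag_runs(x$retained_cross %||%
        integer(0)), sep = "")
  if (length(x$retained_auto))
    cat("; auto: ", format_lag_runs(x$retained_auto), sep = "")
  cat("\n  summed beta = ", signif(sum(x$coefficients$estimate), 4),
      ", loglik = ", round(x$loglik, 2), ", BIC = ", round(x$BIC, 2),
      ", n = ", x$n_obs, "\n", sep = "")
  invisible(x)
}

# residualized design for the next screening cycle: outcome minus the
# currently retained lag contributions (days with a needed-but-missing lag
# term yield a missing residual)
residual_design <- function(design, fit, which = c("cross", "auto")) {
  which <- match.arg(which)
  cc <- fit$coefficients
  mu <- fit$mu
  pred_var <- if (which == "cross") design$predictor else design$outcome
  out <- purrr::imap(design$series, function(s, id) {
    x <- s$M[, design$predictor]
    y <- s$M[, design$outcome]
    r <- y - if (!is.na(mu[id])) mu[id] else 0
    for (j in seq_len(nrow(cc))) {
      src <- if (cc$path[j] == "cross") x else y
      l <- cc$lag[j]
      Tn <- length(y)
      lagged <- c(rep(NA_real_, l), src[seq_len(Tn - l)])
      r <- r - cc$estimate[j] * lagged
    }
    tibble::tibble(subject_id = id, date = s$dates,
                   xvar = s$M[, pred_var], resid = r)
  })
  out <- dplyr::bind_rows(out)
  out <- out[!is.na(out$xvar) | !is.na(out$resid), ]
  build_lag_design(out, "xvar", "resid", design$max_lag)
}

#' Two-stage exploratory-confirmatory lag estimation
#'
#' Alternates the exploratory smooth screening ([fit_smooth_lag()] +
#' [select_lags()]) with the confirmatory discrete-lag fit
#' ([fit_lag_model()]), re-screening the confirmatory residuals for missed
#' lags each cycle, until the retained lag set repeats. On oscillation
#' between two sets their intersection is taken (conservative) and the trace
#' flagged. Auto-regression analysis is the special case
#' `predictor == outcome`.
#'
#' @param panel a standardized panel.
#' @param predictor,outcome variable names (equal for auto-regression).
#' @param max_lag lag window (default 20 days).
#' @param alpha significance level for screening and pruning (default 0.05).
#' @param k spline basis dimension for the exploratory stage (default 19).
#' @param include_auto also screen and include auto-lags of the outcome in
#'   the cross-lag confirmatory fit (default `FALSE`: purely bivariate
#'   model).
#' @param max_iter cycle cap (default 10).
#' @param engine exploratory fitting engine, see [fit_smooth_lag()].
#' @return a `final_lag_model`: the last `lag_model_fit` plus the iteration
#'   trace and convergence status.
#' @export
iterate_two_stage <- function(panel, predictor, outcome, max_lag = 20,
                              alpha = 0.05, k = 19, include_auto = FALSE,
                              max_iter = 10, engine = "auto") {
  stopifnot(max_iter >= 1)
  design <- build_lag_design(panel, predictor, outcome, max_lag)
  selfreg <- predictor == outcome
  auto_design <- if (include_auto && !selfreg)
    build_lag_design(panel, outcome, outcome, max_lag) else NULL

  R_cross <- R_auto <- integer(0)
  fit <- NULL
  trace <- list()
  converged <- FALSE
  oscillation <- FALSE
  history <- list()

  for (it in seq_len(max_iter)) {
    scr <- if (is.null(fit) || !nrow(fit$coefficients)) design
           else residual_design(design, fit, "cross")
    sf <- fit_smooth_lag(scr, k = k, engine = engine)
    C_cross <- sort(union(if (selfreg) R_auto else R_cross,
                          as.integer(select_lags(sf, alpha))))
    C_auto <- integer(0)
    if (!is.null(auto_design)) {
      scr_a <- if (is.null(fit) || !nrow(fit$coefficients)) auto_design
               else residual_design(design, fit, "auto")
      sa <- fit_smooth_lag(scr_a, k = k, engine = engine)
      C_auto <- sort(union(R_auto, as.integer(select_lags(sa, alpha))))
    }
    if (selfreg) {
      C_auto <- C_cross
      C_cross <- integer(0)
    }

    no_candidates <- !length(C_cross) && !length(C_auto)
    reuse <- !is.null(fit) &&
      setequal(if (selfreg) C_auto else C_cross,
               if (selfreg) R_auto else R_cross) &&
      setequal(C_auto, R_auto) && !no_candidates
    if (!reuse) {
      fit <- fit_lag_model(design,
                           candidate_lags = if (selfreg) C_auto else C_cross,
                           auto_lags = if (selfreg) integer(0) else C_auto,
                           alpha = alpha)
    }
    R_new_cross <- fit$retained_cross
    R_new_auto <- fit$retained_auto
    trace[[it]] <- list(
      candidates_cross = if (selfreg) integer(0) else C_cross,
      candidates_auto = if (selfreg) C_auto else C_auto,
      retained_cross = R_new_cross, retained_auto = R_new_auto)
    history[[it]] <- list(cross = R_new_cross, auto = R_new_auto)

    same <- setequal(R_new_cross, R_cross) && setequal(R_new_auto, R_auto)
    if (same && (it > 1 || (length(R_new_cross) + length(R_new_auto) == 0))) {
      converged <- TRUE
      break
    }
    if (reuse) { converged <- TRUE; break }
    if (it >= 3) {
      two_back <- history[[it - 2]]
      if (setequal(R_new_cross, two_back$cross) &&
          setequal(R_new_auto, two_back$auto)) {
        oscillation <- TRUE
        keep_cross <- intersect(R_new_cross, R_cross)
        keep_auto <- intersect(R_new_auto, R_auto)
        fit <- fit_lag_model(design,
                             candidate_lags = if (selfreg) keep_auto
                                              else keep_cross,
                             auto_lags = if (selfreg) integer(0)
                                         else keep_auto,
                             alpha = alpha)
        converged <- TRUE
        break
      }
    }
    R_cross <- R_new_cross
    R_auto <- R_new_auto
  }

  structure(list(fit = fit, trace = trace, converged = converged,
                 oscillation = oscillation, n_cycles = length(trace),
                 predictor = predictor, outcome = outcome,
                 max_lag = max_lag, alpha = alpha,
                 include_auto = include_auto),
            class = "final_lag_model")
}

#' @export
print.final_lag_model <- function(x, ...) {
  cat("Two-stage lag model (", x$n_cycles, " cycle(s), ",
      if (x$converged) "converged" else "not converged",
      if (x$oscillation) ", oscillation resolved by intersection" else "",
      ")\n", sep = "")
  print(x$fit)
  invisible(x)
}
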