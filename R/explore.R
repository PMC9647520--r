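# exploratory stage: smooth lag-coefficient screening via a
# varying-coefficient GAMM

#' Fit a smooth coefficient function over the lag window
#'
#' Exploratory screening stage. On the long-stacked view of a lag design
#' (one row per observed (outcome day, lag) pair) it fits
#' \deqn{y_t = f(l)\, x_{t-l} + u_{subject} + \epsilon}
#' where `f` is a penalized cubic B-spline in the lag index (basis dimension
#' `k`, second-order difference penalty) and the subject effect is a
#' ridge-penalized intercept (formally a mixed-model random intercept). The
#' smoothing parameter is selected by generalized cross-validation.
#' Pointwise Wald statistics at each integer lag come from the penalized-fit
#' (Bayesian) covariance. Each outcome day is reused across lag rows, but
#' for a single lag's coefficient every day contributes once, so pointwise
#' model-based tests stay correctly sized; the duplication matters only for
#' the joint correlation across lags, which the simultaneous band absorbs.
#' A cluster-robust covariance (clustered on subject-day) is available via
#' `robust = TRUE` for sensitivity runs.
#'
#' @param design a [build_lag_design()] result.
#' @param k spline basis dimension (default 19, the lag window minus one).
#' @param sp fixed smoothing parameter(s) passed to [mgcv::gam()]; `NULL`
#'   (default) selects by GCV. Supply `0` for an unpenalized fit.
#' @param subject_effect `"re"` (ridge-penalized subject intercepts) or
#'   `"none"`.
#' @param robust use cluster-robust standard errors (cluster = subject-day)
#'   instead of the default model-based (Bayesian) covariance.
#' @param engine `"gam"`, `"bam"` or `"auto"` (bam above 40000 rows).
#' @param method smoothing-parameter selection criterion passed to mgcv;
#'   defaults to `"GCV.Cp"` for the gam engine and to fast REML
#'   (`"fREML"`, with discretized covariates) for the bam engine.
#' @return a `smooth_lag_fit` tibble with one row per integer lag:
#'   `lag`, `estimate`, `std.error`, `statistic`, `p.value`; attributes hold
#'   the basis dimension, selected smoothing parameter(s), effective degrees
#'   of freedom and subject-effect variance.
#' @export
fit_smooth_lag <- function(design, k = 19, sp = NULL,
                           subject_effect = c("re", "none"),
                           robust = FALSE, engine = c("auto", "gam", "bam"),
                           method = NULL) {
  stopifnot(inherits(design, "lag_design"))
  subject_effect <- match.arg(subject_effect)
  engine <- match.arg(engine)
  long <- design$long
  if (!nrow(long)) stop("empty lag design", call. = FALSE)
  n_lags <- length(unique(long$lag))
  if (n_lags < 4)
    stop("need data at >= 4 distinct lags for the spline basis",
         call. = FALSE)
  if (k > n_lags) k <- n_lags
  L <- design$max_lag
  dat <- data.frame(y = long$y, x = long$x, lag = as.numeric(long$lag),
                    subj = factor(long$subject_id))
  form <- if (subject_effect == "re")
    y ~ s(lag, by = x, bs = "ps", k = k, m = c(2, 2)) + s(subj, bs = "re")
  else
    y ~ s(lag, by = x, bs = "ps", k = k, m = c(2, 2))
  use_bam <- engine == "bam" || (engine == "auto" && nrow(dat) > 40000)
  fitter <- if (use_bam) mgcv::bam else mgcv::gam
  if (is.null(method)) method <- if (use_bam) "fREML" else "GCV.Cp"
  args <- list(formula = form, data = dat, method = method)
  if (use_bam && method == "fREML") args$discrete <- TRUE
  if (!is.null(sp)) {
    nsp <- if (subject_effect == "re") 2L else 1L
    args$sp <- rep_len(sp, nsp)
  }
  fit <- do.call(fitter, args)

  # pointwise coefficient function at integer lags
  nd <- data.frame(lag = as.numeric(seq_len(L)), x = 1,
                   subj = factor(levels(dat$subj)[1],
                                 levels = levels(dat$subj)))
  Xp <- stats::predict(fit, newdata = nd, type = "lpmatrix")
  drop_cols <- grep("s\\(subj\\)|^\\(Intercept\\)", colnames(Xp))
  if (length(drop_cols)) Xp[, drop_cols] <- 0
  beta <- drop(Xp %*% stats::coef(fit))

  if (robust) {
    X <- stats::predict(fit, type = "lpmatrix")
    res <- dat$y - as.numeric(stats::fitted(fit))
    cl <- paste(dat$subj, long$date)
    U <- rowsum(X * res, cl)
    G <- nrow(U)
    meat <- crossprod(U) * G / max(G - 1, 1)
    bread <- fit$Vp / fit$sig2
    V <- bread %*% meat %*% bread
  } else {
    V <- fit$Vp
  }
  C <- Xp %*% V %*% t(Xp)  # joint covariance of the coefficient function
  se <- sqrt(pmax(diag(C), 0))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))

  # simultaneous (across-the-window) p-values: reference distribution of the
  # max absolute standardized deviate of the coefficient function, by
  # simulation from its joint Gaussian (Marra-Wood style bands)
  ok <- se > 0
  p_sim <- rep(NA_real_, L)
  if (any(ok)) {
    Cr <- C[ok, ok, drop = FALSE] / tcrossprod(se[ok])
    ev <- eigen(Cr, symmetric = TRUE)
    Rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(Cr))
    nsim <- 10000L
    mx <- withr::with_seed(1L, {
      E <- Rt %*% matrix(stats::rnorm(nrow(Cr) * nsim), nrow(Cr))
      apply(abs(E), 2, max)
    })
    p_sim[ok] <- vapply(abs(z[ok]), function(zi) mean(mx >= zi), numeric(1))
  }

  out <- tibble::tibble(lag = seq_len(L), estimate = beta, std.error = se,
                        statistic = z, p.value = p, p.sim = p_sim)
  class(out) <- c("smooth_lag_fit", class(out))
  attr(out, "k") <- k
  attr(out, "sp") <- fit$sp
  attr(out, "edf") <- sum(fit$edf)
  attr(out, "gcv") <- fit$gcv.ubre
  attr(out, "n") <- nrow(dat)
  attr(out, "robust") <- robust
  attr(out, "predictor") <- design$predictor
  attr(out, "outcome") <- design$outcome
  sm_re <- if (subject_effect == "re") {
    gv <- tryCatch(
      suppressWarnings(utils::capture.output(
        out_gv <- mgcv::gam.vcomp(fit, rescale = TRUE))) |>
        (\(x) out_gv)(),
      error = function(e) NULL)
    if (is.matrix(gv) && any(grepl("subj", rownames(gv))))
      unname(gv[grep("subj", rownames(gv))[1], 1]^2)
    else NA_real_
  } else 0
  attr(out, "subject_var") <- unname(sm_re)
  out
}

#' Select candidate lags from a smooth lag fit
#'
#' Flags the integer lags whose coefficient-function estimate is significant
#' at level `alpha`. By default significance is assessed against the
#' simultaneous (across-the-window) band of the smooth — the family-wise
#' control that keeps the two-stage procedure conservative; set
#' `simultaneous = FALSE` for pointwise flagging. An empty set is permitted
#' and meaningful (no significant lag identified).
#'
#' @param fit a [fit_smooth_lag()] result (or any tibble with `lag` and
#'   `p.value` / `p.sim` columns).
#' @param alpha significance level (default 0.05).
#' @param simultaneous use the simultaneous-band p-values when available.
#' @return a `lag_set`: integer vector of flagged lags with the level used
#'   as an attribute; printed in run notation (e.g. `"1-3 and 5-6"`).
#' @export
select_lags <- function(fit, alpha = 0.05, simultaneous = TRUE) {
  p <- if (simultaneous && "p.sim" %in% names(fit)) fit[["p.sim"]]
       else fit[["p.value"]]
  lags <- fit$lag[!is.na(p) & p < alpha]
  new_lag_set(as.integer(sort(lags)), alpha)
}

new_lag_set <- function(lags, alpha = 0.05) {
  structure(as.integer(lags), alpha = alpha, class = "lag_set")
}

#' Run notation for a set of integer lags
#'
#' Renders consecutive runs with a dash and joins runs with "and":
#' `c(1,2,3,5,6)` becomes `"1-3 and 5-6"`. The empty set renders as
#' `"n.s."` (no significant lag identified).
#'
#' @param lags integer vector.
#' @return a character scalar.
#' @export
format_lag_runs <- function(lags) {
  lags <- sort(unique(as.integer(lags)))
  if (!length(lags)) return("n.s.")
  grp <- cumsum(c(1L, diff(lags) != 1L))
  runs <- vapply(split(lags, grp), function(r) {
    if (length(r) == 1) as.character(r) else paste0(r[1], "-", r[length(r)])
  }, character(1))
  paste(runs, collapse = " and ")
}

#' @export
print.lag_set <- function(x, ...) {
  cat("<lag_set> ", format_lag_runs(x),
      " (alpha = ", attr(x, "alpha"), ")\n", sep = "")
  invisible(x)
}

#' @export
print.smooth_lag_fit <- function(x, ...) {
  cat("Smooth lag-coefficient fit: ", attr(x, "predictor"), " -> ",
      attr(x, "outcome"), "\n", sep = "")
  cat("  k = ", attr(x, "k"), ", edf = ", round(attr(x, "edf"), 2),
      ", n = ", attr(x, "n"), "\n", sep = "")
  NextMethod()
}
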