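#' Cross-lagged kernel set for the diary simulator
#'
#' A lag kernel assigns to an ordered pair of variables (source -> target) a
#' vector of standardized coefficients \eqn{\beta(l)} for lags
#' \eqn{l = 1, \dots, L}: the per-standard-deviation effect of the source
#' variable \eqn{l} calendar days ago on the target variable today.
#' Unspecified pairs are all-zero. A kernel with source equal to target is an
#' auto-regressive kernel.
#'
#' @param source,target variable names.
#' @param coefs numeric vector of coefficients; element `l` is the effect at
#'   lag `l`. All entries must be smaller than 1 in absolute value.
#' @return a tibble with columns `source`, `target`, `lag`, `beta`.
#' @examples
#' lag_kernel("sleep_quality", "psychosis", c(-0.3, -0.2, -0.1))
#' @export
lag_kernel <- function(source, target, coefs) {
  stopifnot(is.character(source), is.character(target), length(source) == 1,
            length(target) == 1, is.numeric(coefs), length(coefs) >= 1)
  if (any(abs(coefs) >= 1)) {
    stop("kernel coefficients must satisfy |beta(l)| < 1 (pair ",
         source, " -> ", target, ")", call. = FALSE)
  }
  tibble::tibble(source = source, target = target,
                 lag = seq_along(coefs), beta = as.numeric(coefs))
}

#' Simulation configuration for synthetic daily diary panels
#'
#' Defines a multi-subject study in which latent daily series follow a linear
#' Gaussian lagged recursion
#' \deqn{x_{i,t} = c_{i,s} + \sum_{pairs} \sum_l \beta(l)\, src_{i,t-l} + \epsilon_{i,t},}
#' with subject-specific random intercepts \eqn{c_{i,s}} and Gaussian
#' innovations. Defaults emulate a year-long once-daily sleep/symptom diary
#' study in an outpatient psychosis sample: 33 subjects, 323 days each, and a
#' 31\% day-level non-response rate.
#'
#' With `standardize_innovations = TRUE` (default) the innovation variances
#' are calibrated, via the stationary Lyapunov equation of the companion
#' form, so that every latent series has unit stationary (within-person)
#' variance; kernel coefficients are then exactly per-SD effects.
#'
#' @param n_subjects,n_days panel dimensions.
#' @param kernels a list of [lag_kernel()] tibbles (or a single one).
#' @param variables character vector of variable names; defaults to the union
#'   of names in `kernels` (plus `"y"` if empty).
#' @param innovation_sd per-variable innovation SD (recycled); ignored when
#'   `standardize_innovations = TRUE`.
#' @param standardize_innovations calibrate innovation variances to unit
#'   stationary variance per series.
#' @param subject_intercept_sd SD of the per-subject random intercept.
#' @param missing_rate day-level probability of a missing diary, in [0, 1).
#' @param missingness `"mcar"` (days dropped independently) or `"symptom"`
#'   (drop probability increases with the symptom driver's z-score via a
#'   logistic model calibrated to the marginal `missing_rate`).
#' @param missing_slope slope `b` of the logistic non-response model in
#'   `"symptom"` mode (per SD of the driver variable).
#' @param symptom_driver variable driving symptom-dependent non-response.
#' @param likert named integer vector of Likert levels for variables to be
#'   discretized (e.g. `c(sleep_quality = 5, psychosis = 7)`), or `NULL` for
#'   fully continuous observation.
#' @param duration_variable name of the sleep-duration variable (mapped to
#'   hours rather than a Likert scale), or `NULL` if none.
#' @param duration_mean_hours,duration_sd_hours location and scale of the
#'   hours mapping for the duration variable.
#' @param max_lag lag horizon `L` used for the burn-in length; defaults to
#'   the longest kernel.
#' @param seed default RNG seed used by [simulate_panel()].
#' @param start_date calendar date of day 1.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 33, n_days = 323, kernels = list(),
                       variables = NULL, innovation_sd = 1,
                       standardize_innovations = TRUE,
                       subject_intercept_sd = 0.3,
                       missing_rate = 0.31,
                       missingness = c("mcar", "symptom"),
                       missing_slope = 0.5,
                       symptom_driver = "psychosis",
                       likert = NULL,
                       duration_variable = NULL,
                       duration_mean_hours = 7.5, duration_sd_hours = 1.2,
                       max_lag = NULL, seed = 1L,
                       start_date = as.Date("2021-01-04")) {
  missingness <- match.arg(missingness)
  if (inherits(kernels, "data.frame")) kernels <- list(kernels)
  kern <- if (length(kernels)) dplyr::bind_rows(kernels) else
    tibble::tibble(source = character(), target = character(),
                   lag = integer(), beta = numeric())
  if (is.null(variables)) {
    variables <- unique(c(kern$source, kern$target))
    if (!length(variables)) variables <- "y"
  }
  if (!all(kern$source %in% variables) || !all(kern$target %in% variables))
    stop("kernel variables must be listed in `variables`", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (is.null(max_lag)) max_lag <- max(1L, kern$lag)
  if (any(kern$lag > max_lag))
    stop("kernel longer than max_lag", call. = FALSE)
  stopifnot(n_subjects >= 1, n_days >= 2, duration_mean_hours > 0,
            duration_sd_hours > 0, subject_intercept_sd >= 0)
  if (!is.null(likert)) {
    stopifnot(!is.null(names(likert)), all(names(likert) %in% variables),
              all(likert >= 2))
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_days = as.integer(n_days), kernels = kern,
              variables = variables,
              innovation_sd = rep_len(innovation_sd, length(variables)),
              standardize_innovations = isTRUE(standardize_innovations),
              subject_intercept_sd = subject_intercept_sd,
              missing_rate = missing_rate, missingness = missingness,
              missing_slope = missing_slope, symptom_driver = symptom_driver,
              likert = likert, duration_variable = duration_variable,
              duration_mean_hours = duration_mean_hours,
              duration_sd_hours = duration_sd_hours,
              max_lag = as.integer(max_lag), seed = as.integer(seed),
              start_date = start_date)
  class(cfg) <- "sim_config"
  check_stationarity(cfg)
  cfg
}

# companion matrix of the implied VAR over all variables
companion_matrix <- function(cfg) {
  k <- length(cfg$variables)
  L <- cfg$max_lag
  A <- matrix(0, k * L, k * L)
  kern <- cfg$kernels
  for (r in seq_len(nrow(kern))) {
    i <- match(kern$target[r], cfg$variables)
    j <- match(kern$source[r], cfg$variables)
    A[i, (kern$lag[r] - 1) * k + j] <- kern$beta[r]
  }
  if (L > 1) {
    A[(k + 1):(k * L), 1:(k * (L - 1))] <- diag(k * (L - 1))
  }
  A
}

check_stationarity <- function(cfg) {
  if (!nrow(cfg$kernels)) return(invisible(TRUE))
  A <- companion_matrix(cfg)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1 - 1e-8) {
    # try to name the offending pair(s): each kernel alone
    pairs <- unique(paste(cfg$kernels$source, "->", cfg$kernels$target))
    bad <- character()
    for (p in pairs) {
      sub <- cfg$kernels[paste(cfg$kernels$source, "->",
                               cfg$kernels$target) == p, ]
      cfg1 <- cfg
      cfg1$kernels <- sub
      rho1 <- max(Mod(eigen(companion_matrix(cfg1), only.values = TRUE)$values))
      if (rho1 >= 1 - 1e-8) bad <- c(bad, p)
    }
    msg <- if (length(bad)) paste("offending pair(s):", paste(bad, collapse = ", "))
           else "no single pair is explosive; the combination of kernels is"
    stop("kernel set is non-stationary (spectral radius ", signif(rho, 4),
         "); ", msg, call. = FALSE)
  }
  invisible(TRUE)
}

# stationary variance of each series as a linear function of the innovation
# variances, via doubling iterations on the companion Lyapunov equation
stationary_var_map <- function(cfg) {
  k <- length(cfg$variables)
  A <- companion_matrix(cfg)
  M <- matrix(0, k, k)  # M[i, j] = d Var(series i) / d q_j
  for (j in seq_len(k)) {
    Q <- matrix(0, nrow(A), nrow(A))
    Q[j, j] <- 1
    S <- Q
    Ak <- A
    for (it in 1:60) {
      S <- S + Ak %*% S %*% t(Ak)
      Ak <- Ak %*% Ak
      if (max(abs(Ak)) < 1e-14) break
    }
    M[, j] <- diag(S)[seq_len(k)]
  }
  M
}

calibrate_innovations <- function(cfg) {
  k <- length(cfg$variables)
  if (!nrow(cfg$kernels)) return(rep(1, k))
  M <- stationary_var_map(cfg)
  q <- solve(M, rep(1, k))
  if (any(q <= 0)) {
    stop("cannot calibrate unit stationary variance: kernels already ",
         "explain at least the full variance of some series", call. = FALSE)
  }
  sqrt(q)
}

#' Simulate latent daily diary series from known cross-lagged dynamics
#'
#' Generates, for each subject, latent continuous daily series following the
#' configured linear lagged recursion, after discarding a burn-in of
#' `3 * max_lag` days (at least 30) to remove initialization transients.
#' Identical seeds give bit-identical panels; the global RNG state is left
#' untouched.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return an object of class `"true_panel"`: a list with `latent` (tibble of
#'   subject_id, date, day and one column per variable), `subject_means`
#'   (theoretical stationary means per subject/variable), `observed` (filled
#'   in by [discretize_to_likert()] / [apply_missingness()]), and `config`.
#' @export
simulate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  check_stationarity(config)
  k <- length(config$variables)
  L <- config$max_lag
  n <- config$n_subjects
  Tn <- config$n_days
  burn <- max(3L * L, 30L)
  Ttot <- Tn + burn
  sd_inn <- if (config$standardize_innovations) calibrate_innovations(config)
            else config$innovation_sd
  kern <- config$kernels
  ki <- match(kern$target, config$variables)
  kj <- match(kern$source, config$variables)

  withr::with_seed(seed, {
    # per-subject, per-variable intercepts
    icpt <- matrix(stats::rnorm(n * k, 0, config$subject_intercept_sd), n, k)
    # innovations: array [subject, variable, time]
    X <- array(0, dim = c(n, k, Ttot))
    eps <- array(stats::rnorm(n * k * Ttot), dim = c(n, k, Ttot))
    for (t in seq_len(Ttot)) {
      val <- icpt
      for (v in seq_len(k)) val[, v] <- val[, v] + eps[, v, t] * sd_inn[v]
      if (nrow(kern)) {
        for (r in seq_len(nrow(kern))) {
          l <- kern$lag[r]
          if (t - l >= 1) {
            val[, ki[r]] <- val[, ki[r]] + kern$beta[r] * X[, kj[r], t - l]
          }
        }
      }
      X[, , t] <- val
    }
  })
  X <- X[, , (burn + 1):Ttot, drop = FALSE]

  # theoretical stationary means: mu = (I - sum_l A_l)^{-1} c
  Asum <- matrix(0, k, k)
  if (nrow(kern)) for (r in seq_len(nrow(kern)))
    Asum[ki[r], kj[r]] <- Asum[ki[r], kj[r]] + kern$beta[r]
  mu <- t(solve(diag(k) - Asum, t(icpt)))

  subj <- sprintf("S%02d", seq_len(n))
  latent <- tibble::tibble(
    subject_id = rep(subj, each = Tn),
    day = rep(seq_len(Tn), n),
    date = config$start_date + rep(seq_len(Tn), n) - 1L
  )
  for (v in seq_len(k)) {
    latent[[config$variables[v]]] <- as.vector(t(matrix(X[, v, ], nrow = n)))
  }
  colnames(mu) <- config$variables
  means <- tibble::as_tibble(mu)
  means <- dplyr::bind_cols(tibble::tibble(subject_id = subj), means)

  structure(list(latent = latent, observed = NULL, subject_means = means,
                 innovation_sd = sd_inn, config = config),
            class = "true_panel")
}

#' Discretize latent diary series onto their reporting scales
#'
#' Maps each latent value through fixed equal-probability thresholds
#' (standard-normal quantiles of the person-centred latent value) onto the
#' configured Likert levels. The duration variable is instead mapped to hours
#' `mean + sd * latent`, clamped to \[0, 16\] and rounded to the nearest
#' 0.25 h (diary granularity of 15 minutes). Variables without a configured
#' scale are carried through unchanged.
#'
#' @param panel a `"true_panel"` from [simulate_panel()].
#' @param config a [sim_config()]; defaults to the panel's own.
#' @return the panel with `observed` set to the discretized values.
#' @export
discretize_to_likert <- function(panel, config = panel$config) {
  stopifnot(inherits(panel, "true_panel"))
  obs <- panel$latent
  mu <- panel$subject_means
  for (v in config$variables) {
    person_mu <- mu[[v]][match(obs$subject_id, mu$subject_id)]
    z <- obs[[v]] - person_mu  # unit stationary variance by calibration
    if (!is.null(config$duration_variable) && v == config$duration_variable) {
      h <- config$duration_mean_hours + config$duration_sd_hours * z
      h <- pmin(pmax(h, 0), 16)
      obs[[v]] <- round(h / 0.25) * 0.25
    } else if (!is.null(config$likert) && v %in% names(config$likert)) {
      lv <- config$likert[[v]]
      cuts <- stats::qnorm(seq_len(lv - 1) / lv)
      obs[[v]] <- as.integer(findInterval(z, cuts) + 1L)
    }
  }
  panel$observed <- obs
  panel
}

#' Apply day-level diary non-response to a simulated panel
#'
#' Drops whole subject-days (absent rows, never sentinel values). In `"mcar"`
#' mode each day is dropped independently with probability `missing_rate`; in
#' `"symptom"` mode the drop probability is `plogis(a + b * z)` where `z` is
#' the person-centred value of the symptom driver variable and `a` is
#' calibrated so the marginal missing fraction equals `missing_rate`.
#'
#' @inheritParams discretize_to_likert
#' @param seed RNG seed (default derived from the config seed).
#' @return the panel with `observed` reduced to responded days; the
#'   pre-missingness values stay in `latent`.
#' @export
apply_missingness <- function(panel, config = panel$config,
                              seed = config$seed + 1L) {
  stopifnot(inherits(panel, "true_panel"))
  if (config$missing_rate >= 1) stop("missing_rate must be < 1", call. = FALSE)
  obs <- panel$observed %||% panel$latent
  n <- nrow(obs)
  if (config$missing_rate == 0) {
    panel$observed <- obs
    return(panel)
  }
  p <- {
    if (config$missingness == "mcar") {
      rep(config$missing_rate, n)
    } else {
      v <- config$symptom_driver
      if (!v %in% names(obs))
        stop("symptom driver variable `", v, "` not in panel", call. = FALSE)
      mu <- panel$subject_means
      z <- panel$latent[[v]] -
        mu[[v]][match(panel$latent$subject_id, mu$subject_id)]
      z <- z[match(paste(obs$subject_id, obs$day),
                   paste(panel$latent$subject_id, panel$latent$day))]
      b <- config$missing_slope
      f <- function(a) mean(stats::plogis(a + b * z)) - config$missing_rate
      a <- stats::uniroot(f, c(-20, 20))$root
      stats::plogis(a + b * z)
    }
  }
  drop <- withr::with_seed(seed, stats::runif(n) < p)
  panel$observed <- obs[!drop, , drop = FALSE]
  panel
}

#' Simulate an observed diary panel in one call
#'
#' Convenience wrapper: [simulate_panel()], then [discretize_to_likert()]
#' (when scales are configured), then [apply_missingness()]. The returned
#' tibble is the observed panel; the generating `"true_panel"` (latent
#' series, kernels, config) is attached as attribute `"truth"`.
#'
#' @inheritParams simulate_panel
#' @return a tibble with columns `subject_id`, `day`, `date` and one column
#'   per variable.
#' @export
simulate_observed_panel <- function(config, seed = config$seed) {
  tp <- simulate_panel(config, seed = seed)
  if (!is.null(config$likert) || !is.null(config$duration_variable)) {
    tp <- discretize_to_likert(tp)
  }
  tp <- apply_missingness(tp, seed = seed + 1L)
  out <- tp$observed %||% tp$latent
  attr(out, "truth") <- tp
  out
}

#' Write ground-truth kernels to a JSON sidecar
#'
#' @param panel a `"true_panel"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(panel, path) {
  stopifnot(inherits(panel, "true_panel"))
  cfg <- panel$config
  jsonlite::write_json(
    list(variables = cfg$variables,
         kernels = cfg$kernels,
         innovation_sd = panel$innovation_sd,
         n_subjects = cfg$n_subjects, n_days = cfg$n_days,
         missing_rate = cfg$missing_rate, missingness = cfg$missingness,
         seed = cfg$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
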