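# confirmatory state-space lag model

# brute-force oracle: joint-normal marginal likelihood of the observed
# entries, conditioning on the first m0 days (observed init fixed, missing
# init slots ~ N(0, pv)); model
#   x_t = g x_{t-1} + e_x,  y_t = b1 x_{t-1} + b2 x_{t-2} + f1 y_{t-1} + mu + e_y
oracle_ll <- function(Y, g, b1, b2, f1, sx, sy, pv, mu = 0, m0 = 2) {
  Tn <- nrow(Y)
  Z <- list()
  nu <- sum(is.na(Y[1:m0, ])) + 2 * (Tn - m0)
  w0 <- function() numeric(nu)
  ui <- 0
  for (t in 1:m0) for (s in 1:2) {
    if (is.na(Y[t, s])) {
      ui <- ui + 1
      w <- w0(); w[ui] <- sqrt(pv[s])
      Z[[paste(t, s)]] <- list(c0 = 0, w = w)
    } else Z[[paste(t, s)]] <- list(c0 = Y[t, s], w = w0())
  }
  for (t in (m0 + 1):Tn) {
    xm1 <- Z[[paste(t - 1, 1)]]; xm2 <- Z[[paste(t - 2, 1)]]
    ym1 <- Z[[paste(t - 1, 2)]]
    ui <- ui + 1
    wx <- g * xm1$w; wx[ui] <- sx
    Z[[paste(t, 1)]] <- list(c0 = g * xm1$c0, w = wx)
    ui <- ui + 1
    wy <- b1 * xm1$w + b2 * xm2$w + f1 * ym1$w; wy[ui] <- sy
    Z[[paste(t, 2)]] <- list(c0 = b1 * xm1$c0 + b2 * xm2$c0 +
                               f1 * ym1$c0 + mu, w = wy)
  }
  obs <- which(!is.na(Y) & row(Y) > m0, arr.ind = TRUE)
  mu_v <- apply(obs, 1, function(o) Z[[paste(o[1], o[2])]]$c0)
  W <- t(sapply(seq_len(nrow(obs)),
                function(i) Z[[paste(obs[i, 1], obs[i, 2])]]$w))
  S <- W %*% t(W)
  yv <- Y[obs]
  as.numeric(-0.5 * (length(yv) * log(2 * pi) +
                     determinant(S)$modulus[1] +
                     t(yv - mu_v) %*% solve(S, yv - mu_v)))
}

test_that("the filter likelihood equals the joint-normal oracle", {
  set.seed(42)
  Tn <- 12
  g <- 0.4; b1 <- 0.5; b2 <- -0.3; f1 <- 0.2; sx <- 1.1; sy <- 0.8
  x <- numeric(Tn); y <- numeric(Tn)
  for (t in 2:Tn) x[t] <- g * x[t - 1] + rnorm(1, 0, sx)
  for (t in 3:Tn) y[t] <- b1 * x[t - 1] + b2 * x[t - 2] + f1 * y[t - 1] +
    rnorm(1, 0, sy)
  Y <- cbind(x, y)
  Y[c(4, 7), 1] <- NA; Y[c(5, 9, 10), 2] <- NA; Y[1, 1] <- NA
  pv <- c(1.7, 1.3)
  eqs <- rbind(c(1, 1, 1), c(2, 1, 1), c(2, 1, 2), c(2, 2, 1))
  storage.mode(eqs) <- "integer"
  co <- c(g, b1, b2, f1)

  res <- esmlag:::ss_loglik_cpp(list(Y), eqs, co, c(sx, sy), c(2L, 1L),
                                2L, 0L, 2L, pv)
  expect_equal(res$loglik, oracle_ll(Y, g, b1, b2, f1, sx, sy, pv),
               tolerance = 1e-9)

  # concentrated per-subject intercept = profile over the oracle
  res_ic <- esmlag:::ss_loglik_cpp(list(Y), eqs, co, c(sx, sy), c(2L, 1L),
                                   2L, 2L, 2L, pv)
  prof <- stats::optimize(function(m)
    -oracle_ll(Y, g, b1, b2, f1, sx, sy, pv, mu = m), c(-5, 5))
  expect_equal(res_ic$loglik, -prof$objective, tolerance = 1e-7)
  expect_equal(res_ic$mu[1], prof$minimum, tolerance = 1e-4)

  # complete data: outcome part equals the regression log-density
  set.seed(7)
  x2 <- numeric(Tn); y2 <- numeric(Tn)
  for (t in 2:Tn) x2[t] <- g * x2[t - 1] + rnorm(1, 0, sx)
  for (t in 3:Tn) y2[t] <- b1 * x2[t - 1] + b2 * x2[t - 2] +
    f1 * y2[t - 1] + rnorm(1, 0, sy)
  Y2 <- cbind(x2, y2)
  r2 <- esmlag:::ss_loglik_cpp(list(Y2), eqs, co, c(sx, sy), c(2L, 1L),
                               2L, 0L, 2L, pv)
  e <- y2[3:Tn] - b1 * x2[2:(Tn - 1)] - b2 * x2[1:(Tn - 2)] -
    f1 * y2[2:(Tn - 1)]
  expect_equal(r2$loglik_y, sum(stats::dnorm(e, 0, sy, log = TRUE)),
               tolerance = 1e-9)
})

test_that("complete balanced data: ML equals OLS with subject dummies", {
  p <- sim_std_panel(lag_kernel("x", "y", c(-0.4, -0.2, 0.2)), c("x", "y"),
                     n_subjects = 10, n_days = 100, missing_rate = 0,
                     seed = 21)
  d <- build_lag_design(p, "x", "y", max_lag = 3)
  fit <- fit_lag_model(d, candidate_lags = 1:3, prune = FALSE)

  w <- d$wide
  full <- stats::complete.cases(w[paste0("x_lag", 1:3)])
  ols <- stats::lm(y ~ x_lag1 + x_lag2 + x_lag3 + factor(subject_id),
                   data = w[full, ])
  beta_ols <- stats::coef(ols)[paste0("x_lag", 1:3)]
  expect_lt(max(abs(fit$coefficients$estimate - unname(beta_ols))), 1e-6)

  n <- sum(full)
  s2 <- sum(stats::residuals(ols)^2) / n
  ll_closed <- -n / 2 * (log(2 * pi * s2) + 1)
  expect_lt(abs(fit$loglik - ll_closed), 1e-6)
  expect_equal(fit$n_obs, n)
})

test_that("BIC identity holds exactly against independent recomputation", {
  p <- sim_std_panel(lag_kernel("x", "y", c(-0.3, -0.2)), c("x", "y"),
                     n_subjects = 8, n_days = 80, missing_rate = 0.2,
                     seed = 22)
  d <- build_lag_design(p, "x", "y", max_lag = 4)
  fit <- fit_lag_model(d, candidate_lags = 1:2, prune = FALSE)
  expect_identical(fit$BIC,
                   -2 * fit$loglik + fit$n_params * log(fit$n_obs))
  expect_equal(fit$n_params, nrow(fit$coefficients) + 1 + fit$n_subjects)
})

test_that("summed effect is the exact sum of retained coefficients", {
  stub <- structure(list(
    coefficients = tibble::tibble(path = "cross", predictor = "x",
                                  lag = 1:3,
                                  estimate = c(-0.10, -0.05, -0.02),
                                  std.error = 0.01, statistic = -5,
                                  p.value = 0),
    predictor = "x", outcome = "y"), class = "lag_model_fit")
  expect_equal(as.numeric(summed_effect(stub)), -0.17)
  expect_false(attr(summed_effect(stub), "n.s."))

  stub$coefficients <- stub$coefficients[0, ]
  s0 <- summed_effect(stub)
  expect_identical(as.numeric(s0), 0)
  expect_true(attr(s0, "n.s."))

  stub$coefficients <- tibble::tibble(path = "cross", predictor = "x",
                                      lag = 2L, estimate = 0.3,
                                      std.error = 0.01, statistic = 30,
                                      p.value = 0)
  expect_equal(as.numeric(summed_effect(stub)), 0.3)
})

test_that("missing data: true lags are retained and estimated unbiasedly", {
  p <- sim_std_panel(lag_kernel("x", "y", c(-0.3, -0.2)), c("x", "y"),
                     n_subjects = 15, n_days = 200, missing_rate = 0.31,
                     seed = 23)
  d <- build_lag_design(p, "x", "y", max_lag = 6)
  fit <- fit_lag_model(d, candidate_lags = 1:4)
  expect_true(all(c(1, 2) %in% fit$retained_cross))
  cc <- fit$coefficients
  expect_lt(abs(cc$estimate[cc$lag == 1] + 0.3), 0.1)
  expect_lt(abs(cc$estimate[cc$lag == 2] + 0.2), 0.1)
  expect_true(all(cc$p.value < 0.05))
})

test_that("auto-regression recovers an AR(1) through the full two-stage", {
  p <- sim_std_panel(lag_kernel("y", "y", 0.5), "y",
                     n_subjects = 20, n_days = 200, missing_rate = 0,
                     seed = 24)
  fm <- iterate_two_stage(p, "y", "y", max_lag = 10, k = 9)
  expect_true(1 %in% fm$fit$retained_auto)
  phi1 <- fm$fit$coefficients$estimate[fm$fit$coefficients$lag == 1]
  expect_lt(abs(phi1 - 0.5), 0.05)
  expect_true(fm$converged)
})

test_that("an empty candidate set yields a clean null model", {
  p <- sim_std_panel(list(), c("x", "y"), n_subjects = 6, n_days = 60,
                     missing_rate = 0.2, seed = 25)
  d <- build_lag_design(p, "x", "y", max_lag = 5)
  fit <- fit_lag_model(d, candidate_lags = integer(0))
  expect_equal(nrow(fit$coefficients), 0)
  expect_length(fit$retained_cross, 0)
  expect_true(is.finite(fit$BIC))
  s <- summed_effect(fit)
  expect_identical(as.numeric(s), 0)
  expect_true(attr(s, "n.s."))
})

test_that("candidate lags outside the window are rejected", {
  p <- sim_std_panel(list(), c("x", "y"), n_subjects = 4, n_days = 40,
                     seed = 26)
  d <- build_lag_design(p, "x", "y", max_lag = 5)
  expect_error(fit_lag_model(d, candidate_lags = c(1, 9)), "1..max_lag")
})
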