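# synthetic diary generator

test_that("degenerate recursion gives constant-zero latent series", {
  cfg <- sim_config(n_subjects = 3, n_days = 20, kernels = list(),
                    variables = c("x", "y"), innovation_sd = 0,
                    standardize_innovations = FALSE,
                    subject_intercept_sd = 0, missing_rate = 0, seed = 1)
  tp <- simulate_panel(cfg)
  expect_true(all(tp$latent$x == 0))
  expect_true(all(tp$latent$y == 0))
})

test_that("AR(1) kernel reproduces its closed-form lag-1 autocorrelation", {
  # closed form for x_t = 0.5 x_{t-1} + e: corr(x_t, x_{t-1}) = 0.5
  cfg <- sim_config(n_subjects = 30, n_days = 300,
                    kernels = lag_kernel("x", "x", 0.5),
                    innovation_sd = 1, standardize_innovations = FALSE,
                    subject_intercept_sd = 0, missing_rate = 0, seed = 7)
  tp <- simulate_panel(cfg)
  d <- tp$latent
  ac <- sapply(split(d$x, d$subject_id), function(v) {
    stats::cor(v[-1], v[-length(v)])
  })
  expect_lt(abs(mean(ac) - 0.5), 0.05)
})

test_that("identical seed gives bit-identical panels", {
  cfg <- sim_config(n_subjects = 5, n_days = 60,
                    kernels = lag_kernel("x", "y", c(0.2, 0.1)),
                    missing_rate = 0.3, likert = c(x = 7, y = 7), seed = 42)
  a <- simulate_observed_panel(cfg)
  b <- simulate_observed_panel(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("non-stationary kernel sets are rejected naming the pair", {
  expect_error(
    sim_config(kernels = lag_kernel("x", "x", c(0.8, 0.4))),
    "non-stationary.*x -> x")
  # |beta| >= 1 rejected at the kernel level
  expect_error(lag_kernel("x", "y", 1.2), "beta")
})

test_that("unit-variance calibration yields unit stationary variance", {
  cfg <- sim_config(n_subjects = 40, n_days = 400,
                    kernels = list(lag_kernel("x", "x", 0.5),
                                   lag_kernel("x", "y", c(0.3, 0.2))),
                    subject_intercept_sd = 0, missing_rate = 0, seed = 3)
  tp <- simulate_panel(cfg)
  expect_lt(abs(stats::sd(tp$latent$x) - 1), 0.05)
  expect_lt(abs(stats::sd(tp$latent$y) - 1), 0.05)
})

test_that("latent variance is stable over a long run (stationarity guard)", {
  cfg <- sim_config(n_subjects = 4, n_days = 1200,
                    kernels = list(lag_kernel("y", "y", c(0.4, 0.2)),
                                   lag_kernel("x", "y", 0.3)),
                    variables = c("x", "y"), missing_rate = 0, seed = 5)
  tp <- simulate_panel(cfg)
  v <- tapply(tp$latent$y, cut(tp$latent$day, 3), stats::var)
  expect_gt(v[[3]] / v[[2]], 0.5)
  expect_lt(v[[3]] / v[[2]], 2)
})

test_that("Likert discretization maps through equal-probability bins", {
  cfg <- sim_config(n_subjects = 1, n_days = 4, kernels = list(),
                    variables = c("sym", "qual", "sleep_duration"),
                    innovation_sd = 1, standardize_innovations = FALSE,
                    subject_intercept_sd = 0, missing_rate = 0,
                    likert = c(sym = 7, qual = 5),
                    duration_variable = "sleep_duration",
                    duration_mean_hours = 7.5, duration_sd_hours = 1, seed = 1)
  tp <- simulate_panel(cfg)
  tp$latent$sym <- c(0, -10, 10, 0.01)
  tp$latent$qual <- c(0, 10, -10, 0)
  tp$latent$sleep_duration <- c(0, 0.13, -20, 20)
  tp$subject_means[, c("sym", "qual", "sleep_duration")] <- 0
  out <- discretize_to_likert(tp)$observed
  expect_equal(out$sym, c(4L, 1L, 7L, 4L))        # middle category at 0
  expect_equal(out$qual, c(3L, 5L, 1L, 3L))       # clamped at extremes
  expect_equal(out$sleep_duration, c(7.5, 7.75, 0, 16))  # 0.25 h grid, [0,16]
})

test_that("MCAR missingness hits the configured rate within 3 binomial SDs", {
  cfg <- sim_config(n_subjects = 30, n_days = 300, kernels = list(),
                    variables = "y", missing_rate = 0.31, seed = 11)
  obs <- simulate_observed_panel(cfg)
  n <- 30 * 300
  frac <- nrow(obs) / n
  expect_lt(abs(frac - 0.69), 3 * sqrt(0.31 * 0.69 / n))
})

test_that("zero missingness keeps every latent day", {
  cfg <- sim_config(n_subjects = 3, n_days = 50, kernels = list(),
                    variables = "y", missing_rate = 0, seed = 2)
  tp <- apply_missingness(simulate_panel(cfg))
  expect_equal(nrow(tp$observed), nrow(tp$latent))
})

test_that("symptom-dependent non-response selects against high symptom days", {
  cfg <- sim_config(n_subjects = 40, n_days = 300,
                    kernels = lag_kernel("psychosis", "psychosis", 0.3),
                    variables = "psychosis", missing_rate = 0.31,
                    missingness = "symptom", missing_slope = 1, seed = 9)
  tp <- apply_missingness(simulate_panel(cfg))
  expect_lt(mean(tp$observed$psychosis), mean(tp$latent$psychosis))
  # marginal rate still calibrated
  frac_missing <- 1 - nrow(tp$observed) / nrow(tp$latent)
  expect_lt(abs(frac_missing - 0.31),
            3 * sqrt(0.31 * 0.69 / nrow(tp$latent)) + 0.01)
})

test_that("truth sidecar records kernels and seeds", {
  cfg <- sim_config(n_subjects = 2, n_days = 30,
                    kernels = lag_kernel("x", "y", 0.2), seed = 4)
  tp <- simulate_panel(cfg)
  f <- tempfile(fileext = ".json")
  write_truth_json(tp, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$seed, 4)
  expect_equal(j$kernels[[1]]$source, "x")
  unlink(f)
})
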