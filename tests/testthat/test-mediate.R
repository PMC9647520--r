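# lag-space mediation

med_kernels <- function(a = 0.4, b = 0.4) {
  list(lag_kernel("x", "m", a), lag_kernel("m", "y", b))
}

test_that("degenerate triples are rejected", {
  p <- sim_std_panel(list(), c("x", "y"), n_subjects = 4, n_days = 40,
                     seed = 31)
  expect_error(fit_path_a(p, "x", "x"), "differ")
  expect_error(mediation_analysis(p, "x", "x", "y"), "distinct")
})

test_that("full mediation: accounting identity and verdict", {
  cfg <- sim_config(n_subjects = 15, n_days = 180,
                    kernels = med_kernels(), missing_rate = 0.2, seed = 32)
  p <- standardize_panel(simulate_observed_panel(cfg),
                         vars = c("x", "m", "y"))
  mr <- mediation_analysis(p, "x", "m", "y", max_lag = 10, k = 9)
  e <- mr$effects
  expect_identical(e[["indirect"]], e[["total"]] - e[["direct"]])
  expect_gt(length(mr$lags$a), 0)
  expect_gt(length(mr$lags$b), 0)
  expect_true(mr$verdict %in% c("full", "partial"))
  expect_gt(e[["total"]], 0)
  # the oppositional model should not win on data generated forward
  expect_true(mr$comparison$preferred != "oppositional")
})

test_that("no path a means no mediation (short-circuit)", {
  # m unrelated to x: path a empty, verdict fixed before any joint fit
  cfg <- sim_config(n_subjects = 10, n_days = 120,
                    kernels = lag_kernel("m", "y", 0.4),
                    variables = c("x", "m", "y"), missing_rate = 0.2,
                    seed = 33)
  p <- standardize_panel(simulate_observed_panel(cfg),
                         vars = c("x", "m", "y"))
  mr <- mediation_analysis(p, "x", "m", "y", max_lag = 8, k = 7,
                           oppositional = FALSE)
  expect_length(mr$lags$a, 0)
  expect_equal(mr$verdict, "no mediation")
  expect_null(mr$joint)
})

test_that("mediator unrelated to outcome given x: path b not significant", {
  cfg <- sim_config(n_subjects = 10, n_days = 120,
                    kernels = list(lag_kernel("x", "m", 0.4),
                                   lag_kernel("x", "y", 0.4)),
                    missing_rate = 0.2, seed = 34)
  p <- standardize_panel(simulate_observed_panel(cfg),
                         vars = c("x", "m", "y"))
  mr <- mediation_analysis(p, "x", "m", "y", max_lag = 8, k = 7,
                           oppositional = FALSE)
  # m carries x's signal marginally, but given x it adds nothing
  expect_true(mr$verdict %in% c("no mediation", "partial", "none"))
  if (mr$verdict == "no mediation") {
    expect_length(mr$lags$b, 0)
  }
})

test_that("model comparison rules adjudicate indirect pathways and ties", {
  fake <- function(ind, bic) {
    structure(list(has_indirect = ind, bic = c(mediated = bic)),
              class = "mediation_result")
  }
  cmp <- esmlag:::compare_mediation
  expect_equal(cmp(fake(TRUE, 100), fake(FALSE, 90))$preferred, "forward")
  expect_equal(cmp(fake(FALSE, 100), fake(TRUE, 190))$preferred,
               "oppositional")
  expect_equal(cmp(fake(FALSE, 1), fake(FALSE, 2))$preferred, "inconclusive")
  expect_equal(cmp(fake(TRUE, 100), fake(TRUE, 100 + 1e-8))$preferred,
               "inconclusive")
  expect_equal(cmp(fake(TRUE, 100), fake(TRUE, 90))$preferred,
               "oppositional")
  expect_equal(cmp(fake(TRUE, 90), fake(TRUE, 100))$preferred, "forward")
})

test_that("tidy and path output summarise a mediation result", {
  cfg <- sim_config(n_subjects = 10, n_days = 140,
                    kernels = med_kernels(0.5, 0.5), missing_rate = 0,
                    seed = 35)
  p <- standardize_panel(simulate_observed_panel(cfg),
                         vars = c("x", "m", "y"))
  mr <- mediation_analysis(p, "x", "m", "y", max_lag = 8, k = 7)
  td <- tidy(mr)
  expect_equal(nrow(td), 1)
  expect_equal(td$indirect, td$total - td$direct)
  expect_true(td$verdict %in%
                c("full", "partial", "none", "no mediation"))
  lines <- utils::capture.output(pd <- mediation_paths(mr))
  expect_length(pd, 4)
  expect_match(pd[1], "^a ")
  expect_match(pd[4], "direct")
})
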