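# diary reading, cleaning, composites, standardization

test_that("wide CSV reads, rejects out-of-range rows, and reports counts", {
  p <- dplyr::bind_rows(
    diary_row("A", "2021-01-01", quality = 4),
    diary_row("A", "2021-01-02", quality = 2),
    diary_row("B", "2021-01-01", quality = 5))
  f <- write_wide_csv(p)
  panel <- read_diary_csv(f, format = "wide")
  expect_s3_class(panel, "diary_panel")
  expect_equal(nrow(panel), 3)

  bad <- p
  bad$sleep_quality[2] <- 9
  f2 <- write_wide_csv(bad)
  panel2 <- read_diary_csv(f2, format = "wide")
  expect_equal(nrow(panel2), 2)
  expect_equal(cleaning_report(panel2)$rows_rejected, 1)
  unlink(c(f, f2))
})

test_that("empty and unknown-column files fail loudly", {
  f <- tempfile(fileext = ".csv")
  writeLines("subject_id,date", f)
  expect_error(read_diary_csv(f, format = "wide"), "no records")
  p <- diary_row("A", "2021-01-01")
  p$mystery <- 1
  f2 <- write_wide_csv(p)
  expect_error(read_diary_csv(f2, format = "wide"), "unknown column")
  unlink(c(f, f2))
})

test_that("long dialect round-trips losslessly through write and read", {
  p <- dplyr::bind_rows(
    diary_row("A", "2021-01-01", quality = 4, duration = 6.25, item = 2),
    diary_row("A", "2021-01-02", quality = 1, duration = 8, item = 6))
  f <- tempfile(fileext = ".csv")
  write_diary_csv(new_diary_panel_for_test(p), f, format = "long")
  back <- read_diary_csv(f, format = "long")
  expect_equal(back$sleep_duration, p$sleep_duration)
  expect_equal(back$cheerful, p$cheerful)
  f2 <- tempfile(fileext = ".csv")
  write_diary_csv(back, f2, format = "wide")
  back2 <- read_diary_csv(f2, format = "wide")
  expect_equal(sapply(as.data.frame(back2[names(p)]), unclass),
               sapply(as.data.frame(p), unclass))
  unlink(c(f, f2))
})

test_that("duplicate entries within a day are removed keeping the first", {
  p <- dplyr::bind_rows(
    diary_row("A", "2021-01-01", quality = 4),
    diary_row("A", "2021-01-01", quality = 1),
    diary_row("A", "2021-01-01", quality = 2),
    diary_row("A", "2021-01-02", quality = 3))
  d <- dedupe_daily(new_diary_panel_for_test(p))
  expect_equal(nrow(d), 2)
  expect_equal(d$sleep_quality[d$date == as.Date("2021-01-01")], 4)
  expect_equal(cleaning_report(d)$duplicates_removed, 2)
  # idempotent on clean panels
  expect_equal(nrow(dedupe_daily(d)), 2)
})

test_that("composites are the arithmetic means of their items", {
  p <- diary_row("A", "2021-01-01")
  p$cheerful <- 5; p$relaxed <- 3; p$in_control <- 4
  p$suspicious <- 7; p$others_dislike_me <- 1
  p$unusual_sights_sounds <- 2
  cc <- compute_composites(new_diary_panel_for_test(p))
  expect_equal(cc$positive_affect, 4)
  expect_equal(cc$paranoia, 4)
  expect_equal(cc$hallucinations, 2)
  expect_equal(cc$negative_affect, mean(c(p$anxious, p$irritable, p$sad,
                                          p$stressed)))
  expect_equal(cc$psychosis,
               mean(c(7, p$preoccupied_by_thoughts, 1,
                      p$others_influence_thoughts, 2)))
  # a missing constituent leaves the composite absent, not imputed
  p2 <- p
  p2$confused <- NA
  cc2 <- compute_composites(new_diary_panel_for_test(p2))
  expect_true(is.na(cc2$cognitive))
  expect_false(is.na(cc2$positive_affect))
})

test_that("short-enrolment and invariant subjects are excluded with reasons", {
  long_sub <- purrr::map(1:60, function(i)
    diary_row("KEEP", as.Date("2021-01-01") + i - 1,
              quality = 1 + (i %% 5), item = 1 + (i %% 7)))
  short_sub <- purrr::map(1:20, function(i)
    diary_row("SHORT", as.Date("2021-01-01") + i - 1,
              quality = 1 + (i %% 5), item = 1 + (i %% 7)))
  flat_sub <- purrr::map(1:60, function(i)
    diary_row("FLAT", as.Date("2021-01-01") + i - 1, quality = 4, item = 4))
  p <- dplyr::bind_rows(c(long_sub, short_sub, flat_sub))
  cc <- compute_composites(new_diary_panel_for_test(p))
  out <- exclude_subjects(cc, min_days = 30)
  expect_setequal(unique(out$subject_id), "KEEP")
  excl <- cleaning_report(out)$subjects_excluded
  expect_equal(excl$reason[excl$subject_id == "SHORT"], "duration")
  expect_equal(excl$reason[excl$subject_id == "FLAT"], "no variability")
  expect_error(exclude_subjects(cc[cc$subject_id == "FLAT", ], min_days = 30),
               "all subjects excluded")
})

test_that("person-centred z-scores have exact mean 0 and sd 1", {
  p <- tibble::tibble(subject_id = rep(c("A", "B"), each = 3),
                      date = rep(as.Date("2021-01-01") + 0:2, 2),
                      v = c(1, 2, 3, 10, 30, 20))
  z <- standardize_panel(p, vars = "v")
  expect_equal(z$v[1:3], c(-1, 0, 1))  # n-1 denominator
  for (s in c("A", "B")) {
    zi <- z$v[z$subject_id == s]
    expect_lt(abs(mean(zi)), 1e-10)
    expect_lt(abs(stats::sd(zi) - 1), 1e-10)
  }
  # constant series is dropped with a warning
  p$v[4:6] <- 7
  expect_warning(z2 <- standardize_panel(p, vars = "v"), "constant")
  expect_true(all(is.na(z2$v[4:6])))
  expect_equal(z2$v[1:3], c(-1, 0, 1))
})

test_that("the cleaning pipeline is idempotent", {
  set.seed(31)
  p <- dplyr::bind_rows(purrr::map(1:2, function(s)
    dplyr::bind_rows(purrr::map(1:45, function(i)
      diary_row(paste0("S", s), as.Date("2021-01-01") + i - 1,
                quality = sample(1:5, 1), duration = sample(4:9, 1),
                item = sample(1:7, 1))))))
  once <- preprocess_diary(new_diary_panel_for_test(p))
  twice <- suppressWarnings(preprocess_diary(once))
  comps <- names(diary_dictionary()$composites)
  expect_equal(sapply(as.data.frame(twice[comps], check.names = FALSE), c),
               sapply(as.data.frame(once[comps], check.names = FALSE), c),
               tolerance = 1e-12)
})

test_that("response-rate arithmetic respects its bounds", {
  p <- dplyr::bind_rows(
    diary_row("A", "2021-01-01"), diary_row("A", "2021-01-10"),
    diary_row("B", "2021-01-05"))
  sm <- panel_summary(new_diary_panel_for_test(p))
  expect_true(all(sm$submitted <= sm$span_days))
  expect_true(all(sm$response_rate > 0 & sm$response_rate <= 1))
  expect_equal(sm$span_days[sm$subject_id == "A"], 10L)
  expect_equal(sm$response_rate[sm$subject_id == "A"], 0.2)
})
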