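# shared fixtures built in code

# simulated, person-standardized continuous panel
sim_std_panel <- function(kernels, variables, n_subjects, n_days,
                          missing_rate = 0, seed = 1) {
  cfg <- sim_config(n_subjects = n_subjects, n_days = n_days,
                    kernels = kernels, variables = variables,
                    missing_rate = missing_rate, seed = seed)
  obs <- simulate_observed_panel(cfg)
  suppressWarnings(standardize_panel(obs, vars = variables))
}

# minimal wide diary records with all 18 fields valid
diary_row <- function(subject_id, date, quality = 3, duration = 7.5,
                      item = 4) {
  items <- diary_dictionary()$items
  out <- tibble::tibble(subject_id = subject_id, date = as.Date(date),
                        sleep_duration = duration, sleep_quality = quality)
  for (it in items) out[[it]] <- item
  out
}

write_wide_csv <- function(panel, path = tempfile(fileext = ".csv")) {
  readr::write_csv(panel, path, progress = FALSE)
  path
}

new_diary_panel_for_test <- function(x) esmlag:::new_diary_panel(x)
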