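test_that("cumulative incidence reproduces printed-cell arithmetic", {
  expect_equal(cumulative_incidence(7, 151), 4.6)
  expect_equal(cumulative_incidence(23, 201), 11.4)
  expect_equal(cumulative_incidence(0, 155), 0.0)
  expect_equal(cumulative_incidence(107, 156), 68.6)
  expect_true(is.na(cumulative_incidence(0, 0)))
})

test_that("rounding is half-up, not banker's", {
  expect_equal(hepatosafe:::round_half_up(0.25, 1), 0.3)
  expect_equal(hepatosafe:::round_half_up(0.35, 1), 0.4)
  expect_equal(cumulative_incidence(1, 40), 2.5)   # 2.50 stays 2.5
  expect_equal(cumulative_incidence(7, 200), 3.5)  # 3.50 -> 3.5
})

test_that("Clopper-Pearson intervals reproduce printed cells", {
  expect_equal(exact_binomial_ci(7, 151), c(1.9, 9.3))
  expect_equal(exact_binomial_ci(6, 203), c(1.1, 6.3))
  expect_equal(exact_binomial_ci(23, 201), c(7.4, 16.7))
  expect_equal(exact_binomial_ci(2, 204), c(0.1, 3.5))
  expect_equal(exact_binomial_ci(0, 10)[1], 0)
  expect_equal(exact_binomial_ci(10, 10)[2], 100)
})

test_that("the zero-case upper bound follows the one-sided 97.5% formula", {
  expect_equal(zero_case_upper_bound(1), 97.5)
  expect_equal(zero_case_upper_bound(155), 2.351825, tolerance = 1e-6)
  expect_equal(zero_case_upper_bound(122), 2.978416, tolerance = 1e-6)
  ns <- c(5, 20, 80, 320, 1280)
  expect_true(all(diff(zero_case_upper_bound_vec <-
                         vapply(ns, zero_case_upper_bound, double(1))) < 0))
  # identity with the exact binomial upper limit at zero cases, via the
  # independent beta-quantile route
  for (n in c(3, 10, 155, 500)) {
    expect_equal(zero_case_upper_bound(n), 100 * qbeta(0.975, 1, n),
                 tolerance = 1e-10)
  }
})

test_that("person-time sums inclusive episode days with event censoring", {
  one_year <- tibble::tibble(start = day0, end = day0 + 364)
  expect_equal(person_time(one_year), 365 / 365.25)
  two <- tibble::tibble(start = day0 + c(0, 61), end = day0 + c(29, 90))
  expect_equal(person_time(two), 60 / 365.25)
  expect_equal(person_time(one_year, event_date = day0 + 100), 101 / 365.25)
  # an event in the second episode keeps all of the first
  expect_equal(person_time(two, event_date = day0 + 70),
               (30 + 10) / 365.25)
  expect_error(person_time(two, event_date = day0 + 40),
               class = "hepatosafe_contract_error")
  expect_equal(person_time(NULL), 0)
})

test_that("incidence rates carry exact Poisson intervals", {
  expect_equal(incidence_rate(0, 10)$rate, 0)
  r <- incidence_rate(2, 25)
  expect_equal(r$rate, 8.0)
  expect_equal(r$lo, 0.9688371, tolerance = 1e-6)
  expect_equal(r$hi, 28.89875, tolerance = 1e-6)
  expect_true(is.na(incidence_rate(0, 0)$rate))
  expect_error(incidence_rate(2, 0))
})

test_that("time-to-event summaries report mean and median days", {
  s <- time_to_event_summary(61)
  expect_equal(c(s$mean_days, s$median_days), c(61, 61))
  s <- time_to_event_summary(c(38, 73, 109))
  expect_equal(s$mean_days, 73.33333, tolerance = 1e-5)
  expect_equal(s$median_days, 73)
  s <- time_to_event_summary(c(10, 20, 30, 40))
  expect_equal(s$median_days, 25)
  empty <- time_to_event_summary(integer())
  expect_equal(empty$n_events, 0L)
  expect_true(is.na(empty$mean_days) && is.na(empty$median_days))
})

test_that("Clopper-Pearson empirical coverage meets the nominal level", {
  set.seed(5150)
  n <- 150
  p <- 0.05
  reps <- 10000
  x <- rbinom(reps, n, p)
  lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  coverage <- mean(lo <= p & p <= hi)
  mc_se <- sqrt(0.95 * 0.05 / reps)
  expect_gte(coverage, 0.95 - 3 * mc_se)
})

test_that("the incidence table censors person-time per category", {
  # one patient, one year of pazopanib, an ALT 3.5x event on day 30:
  # 31 days count toward the aminotransferase >=3x cell but the full year
  # toward bilirubin cells
  labs <- list(date = day0 + c(-5, -5, 30),
               analyte = c("ALT", "BILI", "ALT"),
               multiple = c(0.6, 0.5, 3.5))
  ds <- mini_dataset(day0 + seq(0, 360, by = 30), labs = labs)
  cfg <- study_config()
  cohort <- select_new_users(ds, cfg)
  expect_equal(nrow(cohort), 1)
  episodes <- build_patient_episodes(ds, cohort, cfg)
  outc <- analyze_outcomes(ds, cohort, episodes, cfg)
  cells <- build_incidence_table(cohort, episodes, outc, cfg)
  alt_cell <- cells[cells$category == "ALT/AST >=3x" &
                      cells$stratum == "overall" &
                      cells$drug == "pazopanib", ]
  expect_equal(alt_cell$n_cases, 1)
  expect_equal(alt_cell$person_years, 31 / 365.25)
  bili_cell <- cells[cells$category == "BILI >=2x" &
                       cells$stratum == "overall" &
                       cells$drug == "pazopanib", ]
  expect_equal(bili_cell$n_cases, 0)
  expect_equal(bili_cell$person_years, 390 / 365.25)
  # zero-case cell carries the one-sided 97.5% upper bound
  expect_equal(bili_cell$cum_inc_lo, 0)
  expect_equal(bili_cell$cum_inc_hi, 97.5)
})

test_that("incidence cells satisfy their accounting invariants", {
  sim <- simulation_config(
    n_patients = c(pazopanib = 20, sorafenib = 12, sunitinib = 15,
                   bevacizumab = 8),
    switch_probability = 0, seed = 77L)
  ds <- generate_dataset(sim)
  cfg <- study_config()
  cohort <- select_new_users(ds, cfg)
  episodes <- build_patient_episodes(ds, cohort, cfg)
  outc <- analyze_outcomes(ds, cohort, episodes, cfg)
  cells <- build_incidence_table(cohort, episodes, outc, cfg)
  expect_equal(nrow(cells), 4 * (nrow(threshold_catalog()) + 1) * 3)
  expect_true(all(cells$n_cases <= cells$n_evaluated))
  expect_true(all(cells$person_years >= 0))
  # uncensored exposure bounds every censored cell of the same stratum
  total_py <- sum(as.integer(episodes$end - episodes$start) + 1) / 365.25
  expect_true(all(cells$person_years <= total_py + 1e-9))
  # line strata partition the overall counts
  overall <- cells[cells$stratum == "overall", ]
  for (i in seq_len(nrow(overall))) {
    parts <- cells[cells$drug == overall$drug[i] &
                     cells$category == overall$category[i] &
                     cells$stratum != "overall", ]
    expect_equal(sum(parts$n_cases), overall$n_cases[i])
    expect_equal(sum(parts$n_evaluated), overall$n_evaluated[i])
    expect_equal(sum(parts$person_years), overall$person_years[i])
  }
  # an ineligible patient appears in neither numerator nor denominator
  elig <- outc$eligibility
  bad <- elig[!elig$eligible, ]
  if (nrow(bad) > 0) {
    j <- 1
    cell <- cells[cells$drug == bad$drug[j] &
                    cells$category == bad$label[j] &
                    cells$stratum == "overall", ]
    n_elig <- sum(elig$eligible[elig$drug == bad$drug[j] &
                                  elig$label == bad$label[j]])
    expect_equal(cell$n_evaluated, n_elig)
  }
})
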