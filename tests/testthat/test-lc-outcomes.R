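catalog <- threshold_catalog()

test_that("ULN multiples are value over ULN and require a positive ULN", {
  expect_equal(uln_multiple(80, 40), 2.0)
  expect_equal(uln_multiple(40, 40), 1.0)
  expect_equal(uln_multiple(0, 40), 0.0)
  expect_error(uln_multiple(40, 0), class = "hepatosafe_validation_error")
})

test_that("baseline multiple is the in-window maximum, absent when unmeasured", {
  labs <- tibble::tibble(patient_id = "p",
                         date = day0 + c(-20, -5, -40),
                         analyte = "ALT",
                         value = c(1.2, 2.1, 9.0) * 40, uln = 40)
  expect_equal(baseline_multiple(labs, "ALT", day0), 2.1)
  on_start <- tibble::tibble(patient_id = "p", date = day0, analyte = "BILI",
                             value = 1.8, uln = 1.2)
  expect_equal(baseline_multiple(on_start, "BILI", day0), 1.5)
  expect_true(is.na(baseline_multiple(labs, "BILI", day0)))
  # ALT_or_AST pools both aminotransferases
  both <- tibble::tibble(patient_id = "p", date = day0 - 3,
                         analyte = c("ALT", "AST"),
                         value = c(1.0, 2.5) * 40, uln = 40)
  expect_equal(baseline_multiple(both, "ALT_or_AST", day0), 2.5)
})

test_that("a baseline of exactly 3.0x splits eligibility at the 3x boundary", {
  elig <- function(label) {
    category_eligibility(3.0, catalog[catalog$label == label, ])
  }
  expect_false(elig("ALT/AST >=3x-4.99x"))
  expect_false(elig("ALT/AST >=2x"))
  expect_false(elig("ALT/AST >=3x"))
  expect_true(elig("ALT/AST >=5x-9.99x"))
  expect_true(elig("ALT/AST >=5x"))
  expect_true(elig("ALT/AST >=8x"))
  expect_true(elig("ALT/AST >=10x"))
  # >-type lower bounds: a baseline equal to the bound stays eligible
  expect_true(category_eligibility(1.0, catalog[catalog$label == "BILI >1x", ]))
  expect_false(category_eligibility(1.01,
                                    catalog[catalog$label == "BILI >1x", ]))
  expect_true(category_eligibility(NA_real_, catalog[1, ]))
})

test_that("catalog membership matches hand-derived range sets", {
  matched <- function(analyte, v) {
    sub <- catalog[catalog$analyte == analyte, ]
    hits <- vapply(seq_len(nrow(sub)), function(k) {
      hepatosafe:::in_category(v, sub[k, ])
    }, logical(1))
    sub$label[hits]
  }
  aa <- function(x) paste("ALT/AST", x)
  expect_setequal(matched("ALT_or_AST", 2.5), aa(">=2x"))
  expect_setequal(matched("ALT_or_AST", 3.0),
                  aa(c(">=3x-4.99x", ">=2x", ">=3x")))
  expect_setequal(matched("ALT_or_AST", 4.99),
                  aa(c(">=3x-4.99x", ">=2x", ">=3x")))
  expect_setequal(matched("ALT_or_AST", 6.0),
                  aa(c(">=5x-9.99x", ">=2x", ">=3x", ">=5x")))
  expect_setequal(matched("ALT_or_AST", 9.99),
                  aa(c(">=5x-9.99x", ">=2x", ">=3x", ">=5x", ">=8x")))
  expect_setequal(matched("ALT_or_AST", 10),
                  aa(c(">=2x", ">=3x", ">=5x", ">=8x", ">=10x")))
  expect_setequal(matched("ALP", 1.0), character())
  expect_setequal(matched("ALP", 1.5), "ALP >1x")
  expect_setequal(matched("ALP", 2.0), c("ALP >1x", "ALP >=2x-2.99x"))
  expect_setequal(matched("ALP", 2.5),
                  c("ALP >1x", "ALP >2x", "ALP >=2x-2.99x"))
  expect_setequal(matched("ALP", 3.0),
                  c("ALP >1x", "ALP >2x", "ALP >=3x-4.99x"))
  expect_setequal(matched("ALP", 5.0),
                  c("ALP >1x", "ALP >2x", "ALP >3x", "ALP >=5x"))
  expect_setequal(matched("BILI", 1.2), "BILI >1x")
  expect_setequal(matched("BILI", 1.5),
                  c("BILI >1x", "BILI >=1.5x-1.99x"))
  expect_setequal(matched("BILI", 2.0),
                  c("BILI >1x", "BILI >=2x-4.99x", "BILI >=2x"))
  expect_setequal(matched("BILI", 5.0),
                  c("BILI >1x", "BILI >=2x", "BILI >=5x"))
})

test_that("eligibility is monotone in the category lower bound", {
  set.seed(99)
  for (i in seq_len(200)) {
    baseline <- runif(1, 0.2, 12)
    for (analyte in unique(catalog$analyte)) {
      sub <- catalog[catalog$analyte == analyte, ]
      for (inc in c(TRUE, FALSE)) {
        grp <- sub[sub$lower_inclusive == inc, ]
        if (nrow(grp) < 2) next
        elig <- vapply(seq_len(nrow(grp)), function(k) {
          category_eligibility(baseline, grp[k, ])
        }, logical(1))
        # sorted by lower bound, eligibility flips at most once: once a
        # lower bound is reached, all lower thresholds are reached too
        o <- order(grp$lower)
        expect_true(all(diff(elig[o]) >= 0))
      }
    }
  }
})

test_that("first elevation is the chronologically first in-range lab in exposure", {
  eps <- tibble::tibble(start = day0, end = day0 + 364)
  cat3 <- catalog[catalog$label == "ALT/AST >=3x", ]
  labs <- tibble::tibble(patient_id = "p",
                         date = day0 + c(10, 30, 60),
                         analyte = "ALT",
                         value = c(1.0, 3.5, 6.0) * 40, uln = 40)
  ev <- detect_first_elevation(labs, cat3, eps, day0)
  expect_equal(ev$days_to_event, 30L)
  expect_equal(ev$multiple, 3.5)
  # banded category: 6.0x is not an event for the 3x-4.99x band
  band <- catalog[catalog$label == "ALT/AST >=3x-4.99x", ]
  only6 <- tibble::tibble(patient_id = "p", date = day0 + 30,
                          analyte = "ALT", value = 6 * 40, uln = 40)
  expect_null(detect_first_elevation(only6, band, eps, day0))
  expect_equal(detect_first_elevation(
    only6, catalog[catalog$label == "ALT/AST >=5x-9.99x", ],
    eps, day0)$multiple, 6)
  # labs in a treatment gap between episodes do not qualify
  split_eps <- tibble::tibble(start = day0 + c(0, 100),
                              end = day0 + c(29, 129))
  gap_lab <- tibble::tibble(patient_id = "p", date = day0 + 60,
                            analyte = "ALT", value = 3.5 * 40, uln = 40)
  expect_null(detect_first_elevation(gap_lab, cat3, split_eps, day0))
  # a start-day lab is baseline, not follow-up
  start_lab <- tibble::tibble(patient_id = "p", date = day0,
                              analyte = "ALT", value = 3.5 * 40, uln = 40)
  expect_null(detect_first_elevation(start_lab, cat3, eps, day0))
})

test_that("first-event detection agrees with a full scan on random series", {
  eps <- tibble::tibble(start = day0 + c(0, 120), end = day0 + c(59, 299))
  set.seed(412)
  for (i in seq_len(100)) {
    n <- sample(5:40, 1)
    labs <- tibble::tibble(patient_id = "p",
                           date = day0 + sample(0:320, n, replace = TRUE),
                           analyte = sample(c("ALT", "AST"), n,
                                            replace = TRUE),
                           value = runif(n, 0, 12) * 40, uln = 40)
    k <- sample(nrow(catalog), 1)
    category <- catalog[k, ]
    if (category$analyte != "ALT_or_AST") next
    got <- detect_first_elevation(labs, category, eps, day0)
    # independent full scan over per-day maxima
    daily <- tapply(labs$value / labs$uln, as.integer(labs$date), max)
    days <- as.integer(names(daily))
    in_ep <- (days >= as.integer(day0) & days <= as.integer(day0) + 59) |
      (days >= as.integer(day0) + 120 & days <= as.integer(day0) + 299)
    lo_ok <- if (category$lower_inclusive) daily >= category$lower
             else daily > category$lower
    hi_ok <- if (is.na(category$upper)) TRUE
             else if (category$upper_inclusive) daily <= category$upper
             else daily < category$upper
    hit_days <- days[in_ep & days > as.integer(day0) & lo_ok & hi_ok]
    if (length(hit_days) == 0) {
      expect_null(got)
    } else {
      expect_equal(as.integer(got$event_date), min(hit_days))
    }
  }
})

test_that("the Hy's-law combination requires all three clauses on one day", {
  eps <- tibble::tibble(start = day0, end = day0 + 364)
  triple <- function(alt, bili, alp, alt_day = 10, bili_day = 10,
                     alp_day = 10) {
    tibble::tibble(patient_id = "p",
                   date = day0 + c(alt_day, bili_day, alp_day),
                   analyte = c("ALT", "BILI", "ALP"),
                   value = c(alt * 40, bili * 1.2, alp * 120),
                   uln = c(40, 1.2, 120))
  }
  hit <- detect_hys_law(triple(3.5, 2.2, 1.5), eps, day0)
  expect_equal(hit$alt_or_ast_multiple, 3.5)
  expect_equal(hit$bili_multiple, 2.2)
  expect_null(detect_hys_law(triple(3.5, 2.2, 2.0), eps, day0))
  expect_null(detect_hys_law(triple(2.9, 2.2, 1.5), eps, day0))
  expect_null(detect_hys_law(triple(3.5, 1.9, 1.5), eps, day0))
  # analytes split across days fail at window 0 but pass with a window
  spread <- triple(3.5, 2.2, 1.5, alt_day = 10, bili_day = 12, alp_day = 11)
  expect_null(detect_hys_law(spread, eps, day0))
  expect_false(is.null(detect_hys_law(spread, eps, day0, window_days = 2)))
  # unmeasured ALP defeats the combination unless alp_required = FALSE
  no_alp <- triple(3.5, 2.2, 1.5)[1:2, ]
  expect_null(detect_hys_law(no_alp, eps, day0))
  expect_false(is.null(detect_hys_law(no_alp, eps, day0,
                                      alp_required = FALSE)))
})

test_that("the DILI screen window and triggers follow the protocol", {
  span_start <- day0
  span_end <- day0 + 27
  dx <- function(code, day) {
    tibble::tibble(patient_id = "p", date = day0 + day, icd9 = code)
  }
  no_labs <- tibble::tibble(patient_id = character(),
                            date = as.Date(character()),
                            analyte = character(), value = double(),
                            uln = double())
  # prefix match: 570.2 hits the 570.x family
  got <- screen_dili(no_labs, dx("570.2", 10), span_start, span_end)
  expect_equal(got$trigger, "icd9_code")
  expect_equal(got$detail, "570.2")
  # 90-day boundary: end + 90 inside, end + 91 outside
  expect_equal(nrow(screen_dili(no_labs, dx("573.3", 27 + 90),
                                span_start, span_end)), 1)
  expect_equal(nrow(screen_dili(no_labs, dx("573.3", 27 + 91),
                                span_start, span_end)), 0)
  # unlisted codes never trigger
  expect_equal(nrow(screen_dili(no_labs, dx("571.1", 10),
                                span_start, span_end)), 0)
  # lab combination is strict: >3x with >2x, same day
  labs <- tibble::tibble(patient_id = "p", date = day0 + c(5, 5, 9, 9),
                         analyte = c("ALT", "BILI", "ALT", "BILI"),
                         value = c(3.2 * 40, 2.1 * 1.2, 3.0 * 40, 2.1 * 1.2),
                         uln = c(40, 1.2, 40, 1.2))
  got <- screen_dili(labs, dx("189.0", -60), span_start, span_end)
  expect_equal(got$trigger, "lab_combination")
  expect_equal(got$date, day0 + 5)   # day 9 fails the strict ALT > 3x
})

test_that("a Hy's-law event implies same-day aminotransferase and bilirubin events", {
  ds <- generate_worked_fixture()
  cfg <- study_config()
  cohort <- select_new_users(ds, cfg)
  episodes <- build_patient_episodes(ds, cohort, cfg)
  outc <- analyze_outcomes(ds, cohort, episodes, cfg)
  hys <- outc$events[outc$events$label == "Possible Hy's law", ]
  for (i in seq_len(nrow(hys))) {
    same <- outc$events[outc$events$patient_id == hys$patient_id[i] &
                          outc$events$event_date == hys$event_date[i], ]
    expect_true("ALT/AST >=3x" %in% same$label)
    expect_true("BILI >=2x" %in% same$label)
  }
})
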