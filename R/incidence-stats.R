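#' Cumulative incidence (percent)
#'
#' Cases divided by patients evaluated, as a percentage rounded half-up to
#' one decimal. A zero denominator yields `NA` (an undefined cell, never
#' zero).
#'
#' @param n_cases,n_evaluated integer counts, `0 <= n_cases <= n_evaluated`.
#' @return percent (rounded), or `NA_real_` when `n_evaluated == 0`.
#' @export
cumulative_incidence <- function(n_cases, n_evaluated) {
  stopifnot(n_cases >= 0, n_cases <= max(n_evaluated, n_cases))
  if (n_evaluated == 0) return(NA_real_)
  stopifnot(n_cases <= n_evaluated)
  round_half_up(100 * n_cases / n_evaluated, 1)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from beta-distribution quantiles, in percent,
#' rounded half-up to one decimal.
#'
#' @inheritParams cumulative_incidence
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)` in percent, or `c(NA, NA)` when
#'   `n_evaluated == 0`.
#' @export
exact_binomial_ci <- function(n_cases, n_evaluated, level = 0.95) {
  if (n_evaluated == 0) return(c(NA_real_, NA_real_))
  stopifnot(n_cases >= 0, n_cases <= n_evaluated)
  alpha <- 1 - level
  lo <- if (n_cases == 0) 0 else {
    qbeta(alpha / 2, n_cases, n_evaluated - n_cases + 1)
  }
  hi <- if (n_cases == n_evaluated) 1 else {
    qbeta(1 - alpha / 2, n_cases + 1, n_evaluated - n_cases)
  }
  round_half_up(100 * c(lo, hi), 1)
}

#' One-sided 97.5% upper bound for zero observed cases
#'
#' The exact upper bound `100 * (1 - 0.025^(1/n))` for a cumulative
#' incidence when 0 of `n` evaluated patients had the outcome; identical to
#' the upper limit of the two-sided 95% Clopper-Pearson interval at zero
#' cases. Returned unrounded.
#'
#' @param n_evaluated number of patients evaluated.
#' @return percent upper bound, or `NA_real_` when `n_evaluated == 0`.
#' @export
zero_case_upper_bound <- function(n_evaluated) {
  if (n_evaluated == 0) return(NA_real_)
  100 * (1 - 0.025^(1 / n_evaluated))
}

#' Person-time at risk, censored at the first event
#'
#' Sums the inclusive day counts of the (disjoint, ordered) treatment
#' episodes, truncated at the event date when one is present: days up to
#' and including the event day count. Follow-up across multiple separate
#' episodes is summed.
#'
#' @param episodes tibble with `start`, `end` date columns.
#' @param event_date censoring date (first LC elevation), or `NULL` for
#'   uncensored exposure; must lie inside an episode when given.
#' @param year_length_days days per person-year (default 365.25).
#' @return person-years (double).
#' @export
person_time <- function(episodes, event_date = NULL,
                        year_length_days = 365.25) {
  if (is.null(episodes) || nrow(episodes) == 0) return(0)
  starts <- as.Date(episodes$start)
  ends <- as.Date(episodes$end)
  stopifnot(all(starts <= ends))
  if (is.null(event_date) || is.na(event_date)) {
    days <- sum(as.numeric(ends - starts) + 1)
  } else {
    event_date <- as.Date(event_date)
    if (!any(starts <= event_date & event_date <= ends)) {
      abort("event_date falls outside all exposure episodes",
            class = "hepatosafe_contract_error")
    }
    capped <- pmin(as.numeric(ends), as.numeric(event_date))
    days <- sum(pmax(0, capped - as.numeric(starts) + 1))
  }
  days / year_length_days
}

#' Incidence rate per 100 person-years with exact Poisson CI
#'
#' Rate = 100 * cases / person-years. The confidence interval places exact
#' Poisson (chi-square quantile) bounds on the case count and scales them
#' by person-time: lower `qchisq(alpha/2, 2k)/2`, upper
#' `qchisq(1 - alpha/2, 2k + 2)/2`. Values are returned unrounded.
#'
#' @param n_cases number of first events.
#' @param person_years total censored person-time (years).
#' @param level confidence level (default 0.95).
#' @return list with `rate`, `lo`, `hi` (per 100 person-years); all `NA`
#'   for the undefined 0-case / 0-time cell.
#' @export
incidence_rate <- function(n_cases, person_years, level = 0.95) {
  if (person_years == 0) {
    if (n_cases > 0) abort("positive case count with zero person-time")
    return(list(rate = NA_real_, lo = NA_real_, hi = NA_real_))
  }
  alpha <- 1 - level
  lo_count <- if (n_cases == 0) 0 else qchisq(alpha / 2, 2 * n_cases) / 2
  hi_count <- qchisq(1 - alpha / 2, 2 * n_cases + 2) / 2
  list(rate = 100 * n_cases / person_years,
       lo = 100 * lo_count / person_years,
       hi = 100 * hi_count / person_years)
}

#' Time-to-event summary
#'
#' Arithmetic mean and median (midpoint of the two central values for an
#' even count) of days from drug start to the event.
#'
#' @param days_to_event integer vector of days; may be empty.
#' @return list with `n_events`, `mean_days`, `median_days` (`NA` when no
#'   events: an empty cell renders as "NA").
#' @export
time_to_event_summary <- function(days_to_event) {
  if (length(days_to_event) == 0) {
    return(list(n_events = 0L, mean_days = NA_real_, median_days = NA_real_))
  }
  list(n_events = length(days_to_event),
       mean_days = mean(days_to_event),
       median_days = median(days_to_event))
}

#' Build the incidence table (per drug, category and stratum)
#'
#' One cell per (drug, category, stratum), where the category list is the
#' threshold catalog plus the Hy's-law combination and the strata are
#' `overall`, `first_line` and `second_line_plus`. Denominators exclude
#' category-ineligible patients (those with a baseline multiple already at
#' or above the category's lower threshold); person-years are censored at
#' each patient's first event for that category; cumulative incidence
#' carries an exact binomial CI, replaced by the one-sided 97.5% upper
#' bound when the cell has zero cases.
#'
#' @param cohort output of [select_new_users()].
#' @param episodes output of [build_patient_episodes()].
#' @param outcomes output of [analyze_outcomes()].
#' @param config a [study_config()].
#' @param catalog threshold catalog used by `analyze_outcomes`.
#' @param database_label label for the data source column.
#' @param strata include line-of-therapy strata (default `TRUE`).
#' @return tibble of incidence cells (see fields in the source).
#' @export
build_incidence_table <- function(cohort, episodes, outcomes,
                                  config = study_config(),
                                  catalog = threshold_catalog(),
                                  database_label = "synthetic",
                                  strata = TRUE) {
  labels <- c(catalog$label, hys_law_label)
  strata_levels <- if (strata) c("overall", "first_line", "second_line_plus")
                   else "overall"
  drugs <- config$study_drugs$drug[config$study_drugs$anti_vegf]

  # numeric episode day vectors per entry, for fast censored person-time
  ep_key <- paste(episodes$patient_id, episodes$drug)
  ep_split <- lapply(split(seq_len(nrow(episodes)), ep_key), function(ix) {
    s <- as.numeric(episodes$start[ix])
    e <- as.numeric(episodes$end[ix])
    list(s = s, e = e, total = sum(e - s + 1))
  })
  censored_days <- function(ep, event_date) {
    ev <- as.numeric(event_date)
    if (!any(ep$s <= ev & ev <= ep$e)) {
      abort("event_date falls outside all exposure episodes",
            class = "hepatosafe_contract_error")
    }
    sum(pmax(0, pmin(ep$e, ev) - ep$s + 1))
  }

  cells <- list()
  for (drug_i in drugs) {
    cohort_d <- cohort[cohort$drug == drug_i, ]
    for (label_i in labels) {
      elig <- outcomes$eligibility
      elig_d <- elig[elig$drug == drug_i & elig$label == label_i &
                       elig$eligible, ]
      ev <- outcomes$events
      ev_d <- ev[ev$drug == drug_i & ev$label == label_i, ]
      for (stratum in strata_levels) {
        members <- cohort_d
        if (stratum != "overall") {
          members <- members[members$line_stratum == stratum, ]
        }
        members <- members[members$patient_id %in% elig_d$patient_id, ]
        n_eval <- nrow(members)
        ev_s <- ev_d[ev_d$patient_id %in% members$patient_id, ]
        n_cases <- nrow(ev_s)

        py <- 0
        if (n_eval > 0) {
          keys <- paste(members$patient_id, drug_i)
          days <- vapply(ep_split[keys], function(ep) {
            if (is.null(ep)) 0 else ep$total
          }, double(1))
          if (n_cases > 0) {
            ev_keys <- paste(ev_s$patient_id, drug_i)
            days[match(ev_keys, keys)] <- vapply(seq_len(n_cases), function(j) {
              censored_days(ep_split[[ev_keys[j]]], ev_s$event_date[j])
            }, double(1))
          }
          py <- sum(days) / config$year_length_days
        }

        ci <- cumulative_incidence(n_cases, n_eval)
        if (n_eval == 0) {
          ci_lo <- NA_real_; ci_hi <- NA_real_
        } else if (n_cases == 0) {
          ci_lo <- 0
          ci_hi <- round_half_up(zero_case_upper_bound(n_eval), 1)
        } else {
          b <- exact_binomial_ci(n_cases, n_eval)
          ci_lo <- b[1]; ci_hi <- b[2]
        }
        ir <- if (py > 0 || n_cases == 0) {
          if (py == 0) list(rate = NA_real_, lo = NA_real_, hi = NA_real_)
          else incidence_rate(n_cases, py)
        } else list(rate = NA_real_, lo = NA_real_, hi = NA_real_)

        cells[[length(cells) + 1]] <- tibble(
          database = database_label, drug = drug_i, category = label_i,
          stratum = stratum, n_cases = n_cases, n_evaluated = n_eval,
          person_years = py,
          cum_inc_pct = ci, cum_inc_lo = ci_lo, cum_inc_hi = ci_hi,
          rate_per_100py = if (is.na(ir$rate)) NA_real_
                           else round_half_up(ir$rate, 1),
          rate_lo = if (is.na(ir$lo)) NA_real_ else round_half_up(ir$lo, 1),
          rate_hi = if (is.na(ir$hi)) NA_real_ else round_half_up(ir$hi, 1)
        )
      }
    }
  }
  bind_rows(cells)
}

#' Time-to-event table for selected categories
#'
#' Summarizes days from drug start to the first event for ALT/AST >=3x,
#' bilirubin >=2x and the Hy's-law combination, per drug.
#'
#' @param outcomes output of [analyze_outcomes()].
#' @param config a [study_config()].
#' @param labels category labels to summarize.
#' @return tibble (`drug`, `category`, `n_events`, `mean_days`,
#'   `median_days`).
#' @export
build_time_to_event_table <- function(outcomes, config = study_config(),
                                      labels = c("ALT/AST >=3x",
                                                 "BILI >=2x",
                                                 hys_law_label)) {
  drugs <- config$study_drugs$drug[config$study_drugs$anti_vegf]
  rows <- list()
  for (drug_i in drugs) {
    for (label_i in labels) {
      ev <- outcomes$events
      d <- ev$days_to_event[ev$drug == drug_i & ev$label == label_i]
      s <- time_to_event_summary(d)
      rows[[length(rows) + 1]] <- tibble(
        drug = drug_i, category = label_i, n_events = s$n_events,
        mean_days = s$mean_days, median_days = s$median_days
      )
    }
  }
  bind_rows(rows)
}
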