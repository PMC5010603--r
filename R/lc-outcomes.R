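#' Liver-chemistry threshold catalog
#'
#' The fixed catalog of LC elevation categories, each a ULN-multiple range
#' for one analyte. Aminotransferase categories use the higher of ALT and
#' AST on a given day; banded categories (e.g. `>=3x-4.99x`) match only
#' values inside the band.
#'
#' @return tibble with columns `label`, `analyte` (`ALT_or_AST`, `ALP`,
#'   `BILI`), `lower`, `lower_inclusive`, `upper` (NA when unbounded),
#'   `upper_inclusive`.
#' @export
threshold_catalog <- function() {
  cat_row <- function(analyte, lower, lower_inc, upper, upper_inc) {
    pretty <- function(x) sub("\\.?0+$", "", format(x, nsmall = 2))
    lab <- paste0(if (lower_inc) ">=" else ">", pretty(lower), "x")
    if (!is.na(upper)) lab <- paste0(lab, "-", pretty(upper), "x")
    shown <- c(ALT_or_AST = "ALT/AST", ALP = "ALP", BILI = "BILI")[analyte]
    tibble(label = paste(shown, lab), analyte = analyte, lower = lower,
           lower_inclusive = lower_inc, upper = upper,
           upper_inclusive = upper_inc)
  }
  bind_rows(
    cat_row("ALT_or_AST", 3, TRUE, 4.99, TRUE),
    cat_row("ALT_or_AST", 5, TRUE, 9.99, TRUE),
    cat_row("ALT_or_AST", 2, TRUE, NA, FALSE),
    cat_row("ALT_or_AST", 3, TRUE, NA, FALSE),
    cat_row("ALT_or_AST", 5, TRUE, NA, FALSE),
    cat_row("ALT_or_AST", 8, TRUE, NA, FALSE),
    cat_row("ALT_or_AST", 10, TRUE, NA, FALSE),
    cat_row("ALP", 1, FALSE, NA, FALSE),
    cat_row("ALP", 2, FALSE, NA, FALSE),
    cat_row("ALP", 3, FALSE, NA, FALSE),
    cat_row("ALP", 2, TRUE, 2.99, TRUE),
    cat_row("ALP", 3, TRUE, 4.99, TRUE),
    cat_row("ALP", 5, TRUE, NA, FALSE),
    cat_row("BILI", 1, FALSE, NA, FALSE),
    cat_row("BILI", 1.5, TRUE, 1.99, TRUE),
    cat_row("BILI", 2, TRUE, 4.99, TRUE),
    cat_row("BILI", 2, TRUE, NA, FALSE),
    cat_row("BILI", 5, TRUE, NA, FALSE)
  )
}

# label used for the Hy's-law pseudo-category in incidence tables
hys_law_label <- "Possible Hy's law"

#' ULN multiple of a lab result
#'
#' @param value lab value(s) in lab units.
#' @param uln upper limit(s) of normal in the same units; must be > 0.
#' @return `value / uln` (the xULN multiple).
#' @export
uln_multiple <- function(value, uln) {
  if (any(is.na(uln)) || any(uln <= 0)) {
    abort("uln must be > 0", class = "hepatosafe_validation_error")
  }
  value / uln
}

# does a ULN multiple fall inside a category's range?
in_category <- function(multiple, category) {
  above <- if (category$lower_inclusive) multiple >= category$lower
           else multiple > category$lower
  below <- if (is.na(category$upper)) TRUE
           else if (category$upper_inclusive) multiple <= category$upper
           else multiple < category$upper
  above & below
}

# daily xULN multiple series for one analyte spec ("ALT_or_AST" takes the
# per-day maximum over ALT and AST; repeated same-day results also collapse
# to the maximum)
daily_multiples <- function(labs, analyte) {
  analytes <- if (analyte == "ALT_or_AST") c("ALT", "AST") else analyte
  keep <- labs$analyte %in% analytes
  if (!any(keep)) {
    return(tibble(date = as.Date(character()), multiple = double()))
  }
  m <- uln_multiple(labs$value[keep], labs$uln[keep])
  agg <- tapply(m, as.integer(labs$date[keep]), max)
  days <- as.integer(names(agg))
  o <- order(days)
  tibble::new_tibble(list(date = structure(as.double(days[o]), class = "Date"),
                          multiple = as.double(agg)[o]),
                     nrow = length(days))
}

#' Baseline ULN multiple for one analyte
#'
#' The maximum xULN multiple among the patient's results of the analyte in
#' the inclusive window `[start - window_days, start]`; `NA` when the
#' analyte was not measured in the window. The maximum is the conservative
#' summary for eligibility screening. `analyte = "ALT_or_AST"` pools ALT and
#' AST.
#'
#' @param labs the patient's lab results.
#' @param analyte one of `"ALT"`, `"AST"`, `"ALT_or_AST"`, `"ALP"`,
#'   `"BILI"`.
#' @param start index drug start date.
#' @param window_days baseline lookback (default 30).
#' @return xULN multiple, or `NA` when unmeasured.
#' @export
baseline_multiple <- function(labs, analyte, start, window_days = 30) {
  dm <- daily_multiples(labs, analyte)
  dm <- dm[dm$date >= start - window_days & dm$date <= start, ]
  if (nrow(dm) == 0) NA_real_ else max(dm$multiple)
}

#' Category eligibility given a baseline multiple
#'
#' A patient is ineligible for a category when their baseline multiple
#' already reaches the category's lower threshold (at-or-above for
#' `>=`-type bounds, strictly-above for `>`-type bounds); banded categories
#' use only their lower bound. An unmeasured baseline leaves the patient
#' eligible.
#'
#' @param baseline baseline xULN multiple or `NA`.
#' @param category one row of [threshold_catalog()].
#' @return `TRUE` when eligible.
#' @export
category_eligibility <- function(baseline, category) {
  if (is.na(baseline)) return(TRUE)
  prior <- if (category$lower_inclusive) baseline >= category$lower
           else baseline > category$lower
  !prior
}

# follow-up dates usable for LC outcome detection: strictly after start
# (start-day labs are baseline) and inside an exposure episode of the index
# drug (optionally only the first episode)
exposure_dates_mask <- function(dates, episodes, start,
                                first_episode_only = FALSE) {
  if (is.null(episodes) || nrow(episodes) == 0) return(rep(FALSE, length(dates)))
  eps <- if (first_episode_only) episodes[1, , drop = FALSE] else episodes
  ok <- rep(FALSE, length(dates))
  for (j in seq_len(nrow(eps))) {
    ok <- ok | (dates >= eps$start[j] & dates <= eps$end[j])
  }
  ok & dates > start
}

#' First qualifying LC elevation for one category
#'
#' Scans the patient's follow-up labs (dated strictly after the start date
#' and inside a treatment episode of the index drug) for the first day
#' whose xULN multiple lies inside the category's range. Banded categories
#' require the value inside the band: a 6.0x ALT is an event for
#' `>=5x-9.99x` but not for `>=3x-4.99x`.
#'
#' @param labs the patient's lab results.
#' @param category one row of [threshold_catalog()].
#' @param episodes the entry's episode table.
#' @param start index drug start date.
#' @param first_episode_only restrict detection to the first episode.
#' @return one-row tibble (`event_date`, `days_to_event`, `multiple`) or
#'   `NULL` when no qualifying result exists.
#' @export
detect_first_elevation <- function(labs, category, episodes, start,
                                   first_episode_only = FALSE) {
  dm <- daily_multiples(labs, category$analyte)
  first_elevation_from_dm(dm, category, episodes, start, first_episode_only)
}

first_elevation_from_dm <- function(dm, category, episodes, start,
                                    first_episode_only = FALSE) {
  if (nrow(dm) == 0) return(NULL)
  ok <- exposure_dates_mask(dm$date, episodes, start, first_episode_only) &
    in_category(dm$multiple, category)
  if (!any(ok)) return(NULL)
  i <- which(ok)[1]
  tibble(event_date = dm$date[i],
         days_to_event = as.integer(dm$date[i] - start),
         multiple = dm$multiple[i])
}

# evaluate the Hy's-law combination over a set of candidate dates; window
# of 0 requires same-day concurrency of all three analytes
hys_law_scan <- function(dm, dates, window_days = 0, alp_required = TRUE) {
  aa <- dm$ALT_or_AST
  bi <- dm$BILI
  al <- dm$ALP
  if (window_days == 0) {
    # same-day concurrency: align the three daily series by date
    dates <- sort(dates)
    aa_m <- aa$multiple[match(dates, aa$date)]
    bi_m <- bi$multiple[match(dates, bi$date)]
    al_m <- al$multiple[match(dates, al$date)]
    ok <- !is.na(aa_m) & aa_m >= 3 & !is.na(bi_m) & bi_m >= 2 &
      (if (alp_required) !is.na(al_m) & al_m < 2
       else is.na(al_m) | al_m < 2)
    if (!any(ok)) return(NULL)
    i <- which(ok)[1]
    return(tibble(event_date = dates[i], alt_or_ast_multiple = aa_m[i],
                  bili_multiple = bi_m[i], alp_multiple = al_m[i]))
  }
  for (d in sort(dates)) {
    d <- as.Date(d)
    near <- function(dm) dm[abs(as.numeric(dm$date - d)) <= window_days, ]
    aa_d <- near(aa); bi_d <- near(bi); al_d <- near(al)
    if (nrow(aa_d) == 0 || max(aa_d$multiple) < 3) next
    if (nrow(bi_d) == 0 || max(bi_d$multiple) < 2) next
    if (nrow(al_d) == 0) {
      if (alp_required) next
      alp_m <- NA_real_
    } else {
      alp_m <- max(al_d$multiple)
      if (alp_m >= 2) next
    }
    return(tibble(event_date = d,
                  alt_or_ast_multiple = max(aa_d$multiple),
                  bili_multiple = max(bi_d$multiple),
                  alp_multiple = alp_m))
  }
  NULL
}

#' Detect the first possible Hy's-law combination
#'
#' The laboratory signal of serious hepatocellular injury: ALT or AST >=3x
#' ULN together with total bilirubin >=2x ULN and ALP <2x ULN. By default
#' all three clauses must be satisfied by results on the same calendar day
#' during follow-up inside a treatment episode; when ALP is unmeasured on
#' that day the combination is not satisfied (the ALP clause cannot be
#' verified) unless `alp_required = FALSE`.
#'
#' @inheritParams detect_first_elevation
#' @param window_days allowed day separation between the analytes (0 =
#'   same day).
#' @param alp_required whether an unmeasured ALP defeats the combination.
#' @return one-row tibble (`event_date`, `alt_or_ast_multiple`,
#'   `bili_multiple`, `alp_multiple`) or `NULL`.
#' @export
detect_hys_law <- function(labs, episodes, start, window_days = 0,
                           alp_required = TRUE, first_episode_only = FALSE) {
  dm <- multiples_cache(labs)
  dates <- unique(labs$date)
  dates <- dates[exposure_dates_mask(dates, episodes, start,
                                     first_episode_only)]
  if (length(dates) == 0) return(NULL)
  hys_law_scan(dm, dates, window_days, alp_required)
}

# per-analyte-spec daily multiple cache for one patient's labs
multiples_cache <- function(labs) {
  lapply(setNames(nm = c("ALT_or_AST", "ALP", "BILI")),
         function(a) daily_multiples(labs, a))
}

# baseline Hy's-law combination present in [start - window, start]?
baseline_hys_law <- function(dm, lab_dates, start, window_days = 30,
                             hys_window_days = 0, alp_required = TRUE) {
  dates <- unique(lab_dates)
  dates <- dates[dates >= start - window_days & dates <= start]
  if (length(dates) == 0) return(FALSE)
  !is.null(hys_law_scan(dm, dates, hys_window_days, alp_required))
}

#' Screen for potential DILI events
#'
#' Screens one patient over the full anti-VEGF exposure span (earliest to
#' latest exposure date across all study drugs) plus a post-exposure
#' extension, for (a) same-day ALT >3x ULN concurrent with bilirubin >2x
#' ULN, and (b) any ICD-9 code on the configured potential-DILI list
#' (277.4, 570.x, 572.8, 573.3, 573.8, 576.8, 782.4; prefix matching for
#' 570.x). Screen-positive dates feed an external chart-review and
#' adjudication process; the pipeline itself renders no DILI verdict.
#'
#' @param labs the patient's lab results.
#' @param diagnoses the patient's diagnosis records.
#' @param span_start,span_end earliest and latest anti-VEGF exposure dates.
#' @param extension_days days past `span_end` kept in the window (default
#'   90).
#' @param dili_codes ICD-9 screening code list.
#' @return tibble (`date`, `trigger`, `detail`), zero rows when the screen
#'   is negative.
#' @export
screen_dili <- function(labs, diagnoses, span_start, span_end,
                        extension_days = 90,
                        dili_codes = c("277.4", "570", "572.8", "573.3",
                                       "573.8", "576.8", "782.4")) {
  w_lo <- as.Date(span_start)
  w_hi <- as.Date(span_end) + extension_days
  flags <- list()

  alt <- daily_multiples(labs, "ALT")
  bi <- daily_multiples(labs, "BILI")
  both <- merge(alt, bi, by = "date", suffixes = c("_alt", "_bili"))
  hit <- both$date >= w_lo & both$date <= w_hi &
    both$multiple_alt > 3 & both$multiple_bili > 2
  if (any(hit)) {
    flags[[1]] <- tibble(
      date = as.Date(both$date[hit]),
      trigger = "lab_combination",
      detail = sprintf("ALT %.2fx / BILI %.2fx",
                       both$multiple_alt[hit], both$multiple_bili[hit])
    )
  }
  dx <- diagnoses[diagnoses$date >= w_lo & diagnoses$date <= w_hi &
                    icd9_matches(diagnoses$icd9, dili_codes), ]
  if (nrow(dx)) {
    flags[[length(flags) + 1]] <- tibble(date = dx$date,
                                         trigger = "icd9_code",
                                         detail = dx$icd9)
  }
  if (length(flags)) bind_rows(flags) |> arrange(.data$date) else {
    tibble(date = as.Date(character()), trigger = character(),
           detail = character())
  }
}

#' Classify outcomes for an entire cohort
#'
#' Runs baseline eligibility, first-elevation detection for every catalog
#' category, Hy's-law detection, and the patient-level DILI screen across
#' all cohort entries.
#'
#' @param dataset an `emr_dataset`.
#' @param cohort output of [select_new_users()].
#' @param episodes output of [build_patient_episodes()].
#' @param config a [study_config()].
#' @param catalog threshold catalog (default [threshold_catalog()]).
#' @return list with elements `eligibility` (entry x category eligibility
#'   flags with baseline multiples), `events` (first elevation per entry and
#'   category, including the Hy's-law pseudo-category), and `dili_flags`
#'   (patient-level screen hits).
#' @export
analyze_outcomes <- function(dataset, cohort, episodes,
                             config = study_config(),
                             catalog = threshold_catalog()) {
  lab <- dataset$lab_results
  lab_by <- split(lab, lab$patient_id)
  eps_by <- split(episodes, paste(episodes$patient_id, episodes$drug))
  empty_labs <- empty_emr_tables()$lab_results
  n_entries <- nrow(cohort)
  n_cat <- nrow(catalog)
  labels_all <- c(catalog$label, hys_law_label)

  # columnar accumulators: one eligibility slot per entry x category (+ the
  # Hy's-law pseudo-category), events appended as flat vectors
  elig_base <- matrix(NA_real_, nrow = n_entries, ncol = n_cat + 1)
  elig_flag <- matrix(TRUE, nrow = n_entries, ncol = n_cat + 1)
  ev_pid <- character(); ev_drug <- character(); ev_label <- character()
  ev_date <- double(); ev_days <- integer(); ev_mult <- double()

  for (i in seq_len(n_entries)) {
    pid <- cohort$patient_id[i]
    drug_i <- cohort$drug[i]
    start <- cohort$start_date[i]
    labs_i <- lab_by[[pid]]
    if (is.null(labs_i)) labs_i <- empty_labs
    eps_i <- eps_by[[paste(pid, drug_i)]]
    dm <- multiples_cache(labs_i)

    w_lo <- start - config$baseline_window_days
    base <- vapply(dm, function(d) {
      in_w <- d$date >= w_lo & d$date <= start
      if (any(in_w)) max(d$multiple[in_w]) else NA_real_
    }, double(1))

    base_vec <- base[catalog$analyte]
    prior <- ifelse(catalog$lower_inclusive, base_vec >= catalog$lower,
                    base_vec > catalog$lower)
    eligible <- is.na(base_vec) | !prior
    elig_base[i, seq_len(n_cat)] <- base_vec
    elig_flag[i, seq_len(n_cat)] <- eligible

    # per-spec exposure masks shared across categories of one analyte
    masks <- lapply(dm, function(d) {
      exposure_dates_mask(d$date, eps_i, start, config$first_episode_only)
    })
    for (k in which(eligible)) {
      d <- dm[[catalog$analyte[k]]]
      ok <- masks[[catalog$analyte[k]]] & in_category(d$multiple, catalog[k, ])
      if (any(ok)) {
        j <- which(ok)[1]
        ev_pid <- c(ev_pid, pid); ev_drug <- c(ev_drug, drug_i)
        ev_label <- c(ev_label, catalog$label[k])
        ev_date <- c(ev_date, as.double(d$date[j]))
        ev_days <- c(ev_days, as.integer(d$date[j] - start))
        ev_mult <- c(ev_mult, d$multiple[j])
      }
    }

    hys_eligible <- !baseline_hys_law(dm, labs_i$date, start,
                                      config$baseline_window_days,
                                      config$hys_law_window_days,
                                      config$alp_required)
    elig_flag[i, n_cat + 1] <- hys_eligible
    if (hys_eligible) {
      fu_dates <- unique(labs_i$date)
      fu_dates <- fu_dates[exposure_dates_mask(fu_dates, eps_i, start,
                                               config$first_episode_only)]
      hy <- if (length(fu_dates)) {
        hys_law_scan(dm, fu_dates, config$hys_law_window_days,
                     config$alp_required)
      } else NULL
      if (!is.null(hy)) {
        ev_pid <- c(ev_pid, pid); ev_drug <- c(ev_drug, drug_i)
        ev_label <- c(ev_label, hys_law_label)
        ev_date <- c(ev_date, as.double(hy$event_date))
        ev_days <- c(ev_days, as.integer(hy$event_date - start))
        ev_mult <- c(ev_mult, hy$alt_or_ast_multiple)
      }
    }
  }

  eligibility <- tibble(
    patient_id = rep(cohort$patient_id, each = n_cat + 1),
    drug = rep(cohort$drug, each = n_cat + 1),
    label = rep(labels_all, times = n_entries),
    baseline_multiple = as.vector(t(elig_base)),
    eligible = as.vector(t(elig_flag))
  )
  events <- tibble(patient_id = ev_pid, drug = ev_drug, label = ev_label,
                   event_date = structure(ev_date, class = "Date"),
                   days_to_event = ev_days, multiple = ev_mult)

  # DILI screen: per patient over the union span of all anti-VEGF exposure
  dx_by <- split(dataset$diagnoses, dataset$diagnoses$patient_id)
  empty_dx <- empty_emr_tables()$diagnoses
  dili_rows <- list()
  for (pid in unique(cohort$patient_id)) {
    eps_p <- episodes[episodes$patient_id == pid, ]
    if (nrow(eps_p) == 0) next
    labs_p <- lab_by[[pid]]
    if (is.null(labs_p)) labs_p <- empty_labs
    dx_p <- dx_by[[pid]]
    if (is.null(dx_p)) dx_p <- empty_dx
    flags <- screen_dili(labs_p, dx_p,
                         span_start = min(eps_p$start),
                         span_end = max(eps_p$end),
                         extension_days = config$dili_extension_days,
                         dili_codes = config$dili_codes)
    if (nrow(flags)) {
      dili_rows[[length(dili_rows) + 1]] <-
        flags |> mutate(patient_id = pid, .before = 1)
    }
  }
  dili_flags <- if (length(dili_rows)) bind_rows(dili_rows) else {
    tibble(patient_id = character(), date = as.Date(character()),
           trigger = character(), detail = character())
  }

  list(eligibility = eligibility, events = events, dili_flags = dili_flags)
}
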