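#' Assign exposure intervals to drug records
#'
#' Each record covers the inclusive interval `[date, date + d - 1]` where
#' `d` is the recorded days supply when present and otherwise the drug's
#' imputed duration from the study drug table (30 days for pazopanib and
#' sorafenib, 28 for sunitinib, 14 per bevacizumab administration).
#'
#' @param records tibble of drug records (`drug`, `date`, `days_supply`).
#' @param rules study drug table ([default_study_drugs()]) or a
#'   [study_config()].
#' @return `records` with `start` and `end` date columns appended.
#' @export
assign_exposure_interval <- function(records, rules = default_study_drugs()) {
  if (inherits(rules, "study_config")) rules <- rules$study_drugs
  unknown <- setdiff(unique(records$drug), rules$drug)
  if (length(unknown)) {
    abort(sprintf("no exposure duration configured for drug: %s",
                  paste(unknown, collapse = ", ")),
          class = "hepatosafe_config_error")
  }
  imputed <- setNames(rules$imputed_duration_days, rules$drug)
  d <- ifelse(is.na(records$days_supply),
              imputed[records$drug], records$days_supply)
  records$start <- records$date
  records$end <- records$date + as.integer(d) - 1L
  records
}

#' Build treatment episodes from exposure intervals
#'
#' A continuous course of one drug: consecutive exposure intervals are
#' merged into one episode while the uncovered gap between them is at most
#' `gap_days` (the gap between an interval ending day `e` and the next
#' starting day `s` is `s - e - 1` days, exclusive of both endpoints); a
#' strictly larger gap ends one episode and begins the next. Initiation of
#' an alternate RCC treatment at date `t`, with no index-drug record on or
#' after `t`, truncates the exposure at `t - 1` and terminates episode
#' building; the truncated episode records the alternate drug in
#' `truncated_by`.
#'
#' @param intervals tibble with `start`, `end` date columns for one
#'   (patient, drug), sorted by `start` (an unsorted input is a contract
#'   violation).
#' @param alternate_starts optional tibble with `drug`, `date` columns
#'   giving initiation dates of alternate RCC treatments.
#' @param gap_days maximum bridgeable gap (default 30).
#' @return tibble with columns `start`, `end`, `truncated_by` (NA unless the
#'   episode was cut short by an alternate treatment).
#' @export
build_treatment_episodes <- function(intervals, alternate_starts = NULL,
                                     gap_days = 30) {
  empty <- tibble(start = as.Date(character()), end = as.Date(character()),
                  truncated_by = character())
  if (is.null(intervals) || nrow(intervals) == 0) return(empty)
  if (is.unsorted(as.numeric(intervals$start))) {
    abort("intervals must be sorted by start date",
          class = "hepatosafe_contract_error")
  }
  starts <- intervals$start
  ends <- intervals$end
  truncated_by <- NA_character_

  if (!is.null(alternate_starts) && nrow(alternate_starts) > 0) {
    alternate_starts <- alternate_starts[order(alternate_starts$date), ]
    # an alternate truncates only if no index-drug record follows it
    truncating <- !vapply(alternate_starts$date,
                          function(t) any(starts >= t), logical(1))
    if (any(truncating)) {
      k <- which(truncating)[1]
      t <- alternate_starts$date[k]
      keep <- starts < t
      starts <- starts[keep]
      ends <- ends[keep]
      clip <- ends >= t
      if (any(clip)) {
        ends[clip] <- t - 1L
        truncated_by <- alternate_starts$drug[k]
      }
      if (length(starts) == 0) return(empty)
    }
  }

  ep_start <- starts[1]
  ep_end <- ends[1]
  out_start <- as.Date(character())
  out_end <- as.Date(character())
  for (i in seq_along(starts)[-1]) {
    gap <- as.integer(starts[i] - ep_end) - 1L
    if (gap <= gap_days) {
      ep_end <- max(ep_end, ends[i])
    } else {
      out_start <- c(out_start, ep_start)
      out_end <- c(out_end, ep_end)
      ep_start <- starts[i]
      ep_end <- ends[i]
    }
  }
  out_start <- c(out_start, ep_start)
  out_end <- c(out_end, ep_end)
  eps <- tibble(start = as.Date(out_start), end = as.Date(out_end),
                truncated_by = NA_character_)
  if (!is.na(truncated_by)) {
    eps$truncated_by[nrow(eps)] <- truncated_by
  }
  eps
}

# first record date per drug for one patient's records
first_starts <- function(records) {
  if (nrow(records) == 0) {
    return(tibble(drug = character(), date = as.Date(character())))
  }
  agg <- tapply(as.integer(records$date), records$drug, min)
  tibble(drug = names(agg),
         date = structure(as.double(unname(agg)), class = "Date"))
}

#' Select new-user cohort entries
#'
#' One entry per (patient, anti-VEGF drug) meeting all protocol criteria at
#' the first observed record of that drug (the start date): start inside the
#' accrual window, an RCC diagnosis (ICD-9 189.0/189.1) on or before start,
#' age 18 or older at start, at least one ALT and one bilirubin result
#' within the baseline window `[start - 30, start]`, and no other anti-VEGF
#' drug's treatment episode covering the start date. A patient may enter
#' under different drugs at different times. Exclusions are returned as an
#' attribute with one reason code per rejected (patient, drug) pair.
#'
#' @param dataset an `emr_dataset`.
#' @param config a [study_config()].
#' @return tibble of cohort entries (`patient_id`, `drug`, `start_date`,
#'   `age_at_start`, `sex`, `line_of_therapy`, `line_stratum`,
#'   `metastasis_sites`, `concomitant_meds`), with attribute `exclusions`: a
#'   tibble (`patient_id`, `drug`, `reason`).
#' @export
select_new_users <- function(dataset, config = study_config()) {
  drugs_tab <- config$study_drugs
  vegf_drugs <- drugs_tab$drug[drugs_tab$anti_vegf]
  dr <- dataset$drug_records
  pat <- dataset$patients
  dx <- dataset$diagnoses
  lab <- dataset$lab_results

  entries <- list()
  exclusions <- list()
  candidates <- dr |>
    filter(.data$drug %in% vegf_drugs) |>
    group_by(.data$patient_id, .data$drug) |>
    summarise(start_date = min(.data$date), .groups = "drop") |>
    arrange(.data$patient_id, .data$start_date, .data$drug)
  if (nrow(candidates) == 0) {
    out <- candidates |> mutate(age_at_start = double(), sex = character(),
                                line_of_therapy = integer(),
                                line_stratum = character(),
                                metastasis_sites = list(),
                                concomitant_meds = list())
    attr(out, "exclusions") <- tibble(patient_id = character(),
                                      drug = character(), reason = character())
    return(out)
  }

  empty <- empty_emr_tables()
  dx_by <- split(dx, dx$patient_id)
  lab_by <- split(lab, lab$patient_id)
  dr_by <- split(dr, dr$patient_id)
  birth_by <- setNames(pat$birth_date, pat$patient_id)
  sex_by <- setNames(pat$sex, pat$patient_id)

  for (i in seq_len(nrow(candidates))) {
    pid <- candidates$patient_id[i]
    drug_i <- candidates$drug[i]
    start <- candidates$start_date[i]
    reject <- function(reason) {
      exclusions[[length(exclusions) + 1]] <<-
        tibble(patient_id = pid, drug = drug_i, reason = reason)
    }

    if (start < config$accrual_start || start > config$accrual_end) {
      reject("accrual_window"); next
    }
    dx_i <- dx_by[[pid]]
    if (is.null(dx_i)) dx_i <- empty$diagnoses
    has_rcc <- any(icd9_matches(dx_i$icd9, config$rcc_codes) &
                     dx_i$date <= start)
    if (!has_rcc) { reject("no_rcc_diagnosis"); next }

    age <- floor(as.numeric(start - birth_by[[pid]]) / 365.25)
    if (is.na(age) || age < 18) { reject("age"); next }

    w_lo <- start - config$baseline_window_days
    lab_p <- lab_by[[pid]]
    if (is.null(lab_p)) lab_p <- empty$lab_results
    lab_i <- lab_p[lab_p$date >= w_lo & lab_p$date <= start, ]
    if (!("ALT" %in% lab_i$analyte) || !("BILI" %in% lab_i$analyte)) {
      reject("missing_baseline_lab"); next
    }

    # concurrent-use exclusion: another anti-VEGF drug's (untruncated)
    # episode covers this start date
    dr_i <- dr_by[[pid]]
    other <- dr_i[dr_i$drug %in% vegf_drugs & dr_i$drug != drug_i, ]
    concurrent <- FALSE
    if (nrow(other)) {
      for (od in unique(other$drug)) {
        ints <- assign_exposure_interval(other[other$drug == od, ],
                                         drugs_tab) |>
          arrange(.data$start)
        eps <- build_treatment_episodes(ints, gap_days = config$gap_days)
        if (any(eps$start <= start & start <= eps$end)) {
          concurrent <- TRUE
          break
        }
      }
    }
    if (concurrent) { reject("concurrent_anti_vegf"); next }

    prior <- dr_i[dr_i$drug %in% config$antineoplastic_drugs &
                    dr_i$drug != drug_i & dr_i$date < start,
                  c("drug", "date")]
    line <- derive_line_of_therapy(prior, start,
                                   regimen_window_days =
                                     config$regimen_window_days)
    eps_i <- episodes_for_entry(dr_i, drug_i, start, config)
    mets <- derive_metastases(dx_i, start, config$metastasis_code_map)
    conmeds <- derive_concomitant_meds(dr_i, eps_i, start,
                                       index_drug = drug_i,
                                       window_days =
                                         config$baseline_window_days)
    entries[[length(entries) + 1]] <- tibble(
      patient_id = pid, drug = drug_i, start_date = start,
      age_at_start = age, sex = sex_by[[pid]],
      line_of_therapy = line,
      line_stratum = if (line == 1) "first_line" else "second_line_plus",
      metastasis_sites = list(mets),
      concomitant_meds = list(conmeds)
    )
  }
  out <- if (length(entries)) bind_rows(entries) else {
    tibble(patient_id = character(), drug = character(),
           start_date = as.Date(character()), age_at_start = double(),
           sex = character(), line_of_therapy = integer(),
           line_stratum = character(), metastasis_sites = list(),
           concomitant_meds = list())
  }
  attr(out, "exclusions") <- if (length(exclusions)) bind_rows(exclusions) else {
    tibble(patient_id = character(), drug = character(), reason = character())
  }
  out
}

# episodes for one cohort entry: index-drug intervals, truncation by
# alternates (other anti-VEGF drugs + configured alternate RCC treatments)
# whose first record falls after the index start; dr_i holds one patient's
# drug records
episodes_for_entry <- function(dr_i, drug, start, config) {
  ints <- assign_exposure_interval(dr_i[dr_i$drug == drug, ],
                                   config$study_drugs)
  ints <- ints[order(ints$start), ]
  vegf <- config$study_drugs$drug[config$study_drugs$anti_vegf]
  alt_drugs <- setdiff(union(vegf, config$alternate_rcc_treatments), drug)
  alt <- first_starts(dr_i[dr_i$drug %in% alt_drugs, ])
  alt <- alt[alt$date > start, ]
  build_treatment_episodes(ints, alternate_starts = alt,
                           gap_days = config$gap_days)
}

#' Build treatment episodes for every cohort entry
#'
#' @param dataset an `emr_dataset`.
#' @param cohort output of [select_new_users()].
#' @param config a [study_config()].
#' @return tibble with columns `patient_id`, `drug`, `episode` (1-based
#'   index), `start`, `end`, `truncated_by`.
#' @export
build_patient_episodes <- function(dataset, cohort, config = study_config()) {
  if (nrow(cohort) == 0) {
    return(tibble(patient_id = character(), drug = character(),
                  episode = integer(), start = as.Date(character()),
                  end = as.Date(character()), truncated_by = character()))
  }
  dr_by <- split(dataset$drug_records, dataset$drug_records$patient_id)
  purrr::pmap(list(cohort$patient_id, cohort$drug, cohort$start_date),
              function(pid, drug, start) {
                eps <- episodes_for_entry(dr_by[[pid]], drug, start, config)
                if (nrow(eps) == 0) return(NULL)
                tibble::new_tibble(
                  list(patient_id = rep(pid, nrow(eps)),
                       drug = rep(drug, nrow(eps)),
                       episode = seq_len(nrow(eps)),
                       start = eps$start, end = eps$end,
                       truncated_by = eps$truncated_by),
                  nrow = nrow(eps))
              }) |>
    bind_rows()
}

#' Derive line of therapy at the index drug start
#'
#' Line = 1 + the number of distinct prior regimens, where a regimen groups
#' antineoplastic drug starts falling within `regimen_window_days` of the
#' regimen's first start (combination partners started together count as one
#' regimen).
#'
#' @param prior_treatments tibble with `drug`, `date` of antineoplastic drug
#'   records strictly before `start`.
#' @param start index drug start date.
#' @param regimen_window_days co-start window grouping drugs into one
#'   regimen (default 30).
#' @return integer line of therapy (>= 1).
#' @export
derive_line_of_therapy <- function(prior_treatments, start,
                                   regimen_window_days = 30) {
  if (is.null(prior_treatments) || nrow(prior_treatments) == 0) return(1L)
  stopifnot(all(prior_treatments$date < start))
  starts <- sort(as.integer(first_starts(prior_treatments)$date))
  n_regimens <- 1L
  anchor <- starts[1]
  for (d in starts[-1]) {
    if (d - anchor > regimen_window_days) {
      n_regimens <- n_regimens + 1L
      anchor <- d
    }
  }
  1L + n_regimens
}

#' Derive metastasis sites present at baseline
#'
#' Maps secondary-malignancy ICD-9 codes (196--198) recorded on or before
#' the start date to site labels: lung 197.0, liver 197.7, bone/marrow
#' 198.5, brain/spinal cord 198.3-198.4, adrenal 198.7; any other 196--198
#' code maps to `other`; no qualifying code yields `none`.
#'
#' @param diagnoses tibble of the patient's diagnosis records.
#' @param start index drug start date.
#' @param code_map site-to-prefix map ([default_metastasis_map()]).
#' @return character vector of site labels.
#' @export
derive_metastases <- function(diagnoses, start,
                              code_map = default_metastasis_map()) {
  codes <- diagnoses$icd9[diagnoses$date <= start]
  met_codes <- codes[icd9_matches(codes, c("196", "197", "198"))]
  if (length(met_codes) == 0) return("none")
  sites <- character()
  mapped <- rep(FALSE, length(met_codes))
  for (site in names(code_map)) {
    hits <- icd9_matches(met_codes, code_map[[site]])
    if (any(hits)) sites <- c(sites, site)
    mapped <- mapped | hits
  }
  if (any(!mapped)) sites <- c(sites, "other")
  sites
}

#' Derive concomitant medications
#'
#' Non-index drugs recorded within the baseline window before the start
#' date, or dated inside any treatment episode of the index drug.
#'
#' @param drug_records the patient's drug records.
#' @param episodes the entry's episode table (`start`, `end`).
#' @param start index drug start date.
#' @param index_drug index drug name (excluded).
#' @param window_days baseline lookback (default 30).
#' @return sorted character vector of drug names.
#' @export
derive_concomitant_meds <- function(drug_records, episodes, start,
                                    index_drug, window_days = 30) {
  other <- drug_records[drug_records$drug != index_drug, ]
  if (nrow(other) == 0) return(character())
  in_window <- other$date >= start - window_days & other$date <= start
  in_exposure <- rep(FALSE, nrow(other))
  if (!is.null(episodes) && nrow(episodes) > 0) {
    for (j in seq_len(nrow(episodes))) {
      in_exposure <- in_exposure |
        (other$date >= episodes$start[j] & other$date <= episodes$end[j])
    }
  }
  sort(unique(other$drug[in_window | in_exposure]))
}
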