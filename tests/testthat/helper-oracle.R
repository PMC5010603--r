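# Brute-force day-bitmap oracle for treatment-episode construction: mark
# every covered day on a calendar grid, apply alternate-treatment
# truncation by clearing days, and extract maximal runs of marked days
# allowing up to gap_days unmarked days inside a run. Kept deliberately
# independent of the interval-merging implementation under test.
oracle_episodes <- function(starts, ends, alt_drugs = character(),
                            alt_dates = integer(), gap_days = 30,
                            horizon = 800) {
  marked <- rep(FALSE, horizon + 1)            # index j = day j - 1
  for (i in seq_along(starts)) marked[(starts[i]:ends[i]) + 1] <- TRUE
  truncated_by <- NA_character_
  if (length(alt_dates)) {
    o <- order(alt_dates)
    alt_dates <- alt_dates[o]
    alt_drugs <- alt_drugs[o]
    for (k in seq_along(alt_dates)) {
      t <- alt_dates[k]
      if (any(starts >= t)) next               # an index record follows
      cleared <- marked & (seq_along(marked) - 1 >= t)
      if (any(cleared)) truncated_by <- alt_drugs[k]
      marked[cleared] <- FALSE
      break                                    # episode building terminates
    }
  }
  days <- which(marked) - 1
  if (length(days) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      truncated_by = character()))
  }
  run_start <- days[1]
  prev <- days[1]
  ss <- integer(); ee <- integer()
  for (d in days[-1]) {
    if (d - prev - 1 <= gap_days) {
      prev <- d
    } else {
      ss <- c(ss, run_start); ee <- c(ee, prev)
      run_start <- d; prev <- d
    }
  }
  ss <- c(ss, run_start); ee <- c(ee, prev)
  tb <- rep(NA_character_, length(ss))
  if (!is.na(truncated_by)) tb[length(tb)] <- truncated_by
  data.frame(start = ss, end = ee, truncated_by = tb)
}

# random interval set + alternate starts for the oracle property
random_interval_case <- function() {
  n <- sample(1:10, 1)
  starts <- sort(sample(0:400, n, replace = TRUE))
  ends <- starts + sample(1:60, n, replace = TRUE) - 1
  alt <- NULL
  if (runif(1) < 0.5) {
    m <- sample(1:2, 1)
    alt <- data.frame(drug = sample(c("sunitinib", "everolimus"), m,
                                    replace = TRUE),
                      date = sample(0:450, m))
  }
  list(starts = starts, ends = ends, alt = alt)
}

day0 <- as.Date("2010-01-01")

# compare build_treatment_episodes against the bitmap oracle on one case
expect_matches_oracle <- function(case, gap_days = 30) {
  ints <- tibble::tibble(start = day0 + case$starts, end = day0 + case$ends)
  alt_tbl <- if (is.null(case$alt)) NULL else {
    tibble::tibble(drug = case$alt$drug, date = day0 + case$alt$date)
  }
  got <- build_treatment_episodes(ints, alt_tbl, gap_days = gap_days)
  want <- oracle_episodes(case$starts, case$ends,
                          alt_drugs = if (is.null(case$alt)) character()
                                      else case$alt$drug,
                          alt_dates = if (is.null(case$alt)) integer()
                                      else case$alt$date,
                          gap_days = gap_days)
  expect_equal(as.integer(got$start - day0), want$start)
  expect_equal(as.integer(got$end - day0), want$end)
  expect_equal(got$truncated_by, want$truncated_by)
}

# minimal single-patient dataset builder used across outcome tests
mini_dataset <- function(drug_dates, drug = "pazopanib",
                         labs = NULL, diagnoses = NULL,
                         start = day0, kind = "prescription") {
  lab_tbl <- if (is.null(labs)) NULL else {
    tibble::tibble(patient_id = "P1", date = labs$date,
                   analyte = labs$analyte,
                   value = labs$multiple * 40, uln = 40)
  }
  dx <- tibble::tibble(patient_id = "P1", date = start - 60, icd9 = "189.0")
  if (!is.null(diagnoses)) dx <- dplyr::bind_rows(dx, diagnoses)
  emr_dataset(
    patients = tibble::tibble(patient_id = "P1",
                              birth_date = as.Date("1950-01-01"),
                              sex = "male"),
    diagnoses = dx,
    drug_records = tibble::tibble(patient_id = "P1", drug = drug,
                                  date = drug_dates,
                                  days_supply = NA_integer_, kind = kind),
    lab_results = lab_tbl,
    provenance = "test"
  )
}
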