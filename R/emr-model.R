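#' Study protocol configuration
#'
#' Bundles every protocol-level constant the pipeline uses: the anti-VEGF
#' study drugs with their imputed exposure durations, the accrual window,
#' the day-window lengths (baseline lab lookback, episode gap allowance,
#' post-exposure DILI extension), diagnosis code lists, and the options left
#' open by the protocol (single-day vs windowed Hy's-law concurrency,
#' whether an unmeasured ALP defeats the combination, first-episode-only
#' outcome detection).
#'
#' @param study_drugs tibble with columns `drug`, `anti_vegf` (logical),
#'   `imputed_duration_days`, `kind`; see [default_study_drugs()].
#' @param accrual_start,accrual_end accrual window (cohort entry requires the
#'   first record of the index drug inside `[accrual_start, accrual_end]`).
#' @param baseline_window_days lookback (days) for baseline labs, window
#'   inclusive on both ends: `[start - baseline_window_days, start]`.
#' @param gap_days maximum coverage gap (days) bridged within one treatment
#'   episode; a strictly larger gap splits the course into two episodes.
#' @param dili_extension_days days past the last anti-VEGF exposure date kept
#'   in the DILI screening window.
#' @param rcc_codes ICD-9 codes identifying renal cell carcinoma.
#' @param metastasis_code_map named list mapping metastasis site labels to
#'   ICD-9 code prefixes; any other 196--198 code maps to `"other"`.
#' @param dili_codes ICD-9 codes screened as potential drug-induced liver
#'   injury (prefix matching, so `"570"` captures `570.x`).
#' @param alternate_rcc_treatments non-anti-VEGF RCC drugs whose initiation
#'   truncates an index-drug episode (the other anti-VEGF drugs always do).
#' @param antineoplastic_drugs drug names counted when numbering lines of
#'   therapy; defaults to the study drugs plus the alternates.
#' @param regimen_window_days drug starts within this many days of one
#'   another are grouped into one regimen when deriving line of therapy.
#' @param year_length_days days per person-year.
#' @param first_episode_only restrict LC outcome detection to the first
#'   treatment episode of the index drug (default detects in all episodes).
#' @param hys_law_window_days allowed day separation between the three
#'   Hy's-law analytes; 0 requires all three on the same calendar day.
#' @param alp_required if `TRUE`, the Hy's-law combination fails when no ALP
#'   result is available to verify ALP < 2x ULN.
#' @param seed integer seed recorded in run metadata.
#' @return object of class `study_config` (a named list).
#' @export
study_config <- function(study_drugs = default_study_drugs(),
                         accrual_start = as.Date("2009-10-01"),
                         accrual_end = as.Date("2013-02-17"),
                         baseline_window_days = 30,
                         gap_days = 30,
                         dili_extension_days = 90,
                         rcc_codes = c("189.0", "189.1"),
                         metastasis_code_map = default_metastasis_map(),
                         dili_codes = c("277.4", "570", "572.8", "573.3",
                                        "573.8", "576.8", "782.4"),
                         alternate_rcc_treatments = c("everolimus",
                                                      "temsirolimus",
                                                      "interferon",
                                                      "interleukin-2"),
                         antineoplastic_drugs = NULL,
                         regimen_window_days = 30,
                         year_length_days = 365.25,
                         first_episode_only = FALSE,
                         hys_law_window_days = 0,
                         alp_required = TRUE,
                         seed = 1L) {
  stopifnot(is.data.frame(study_drugs),
            all(c("drug", "anti_vegf", "imputed_duration_days", "kind") %in%
                  names(study_drugs)),
            all(study_drugs$imputed_duration_days >= 1))
  accrual_start <- as.Date(accrual_start)
  accrual_end <- as.Date(accrual_end)
  if (!(accrual_start < accrual_end)) {
    abort("accrual_start must precede accrual_end")
  }
  if (baseline_window_days <= 0 || gap_days <= 0 || dili_extension_days <= 0) {
    abort("all window lengths must be positive")
  }
  if (is.null(antineoplastic_drugs)) {
    antineoplastic_drugs <- union(study_drugs$drug, alternate_rcc_treatments)
  }
  structure(list(
    study_drugs = as_tibble(study_drugs),
    accrual_start = accrual_start,
    accrual_end = accrual_end,
    baseline_window_days = as.integer(baseline_window_days),
    gap_days = as.integer(gap_days),
    dili_extension_days = as.integer(dili_extension_days),
    rcc_codes = rcc_codes,
    metastasis_code_map = metastasis_code_map,
    dili_codes = dili_codes,
    alternate_rcc_treatments = tolower(alternate_rcc_treatments),
    antineoplastic_drugs = tolower(antineoplastic_drugs),
    regimen_window_days = as.integer(regimen_window_days),
    year_length_days = year_length_days,
    first_episode_only = isTRUE(first_episode_only),
    hys_law_window_days = as.integer(hys_law_window_days),
    alp_required = isTRUE(alp_required),
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Default anti-VEGF study drug table
#'
#' The four study drugs with the protocol's imputed exposure durations used
#' when a record carries no days supply: 30 days for pazopanib and
#' sorafenib, 28 days for sunitinib, and 14 days per bevacizumab infusion
#' (the indicated interval between administrations). The oral TKIs appear as
#' prescriptions; bevacizumab as clinic administrations.
#'
#' @return tibble with columns `drug`, `anti_vegf`, `imputed_duration_days`,
#'   `kind`.
#' @export
default_study_drugs <- function() {
  tibble(
    drug = c("pazopanib", "sorafenib", "sunitinib", "bevacizumab"),
    anti_vegf = TRUE,
    imputed_duration_days = c(30L, 30L, 28L, 14L),
    kind = c("prescription", "prescription", "prescription", "administration")
  )
}

#' Default metastasis site map (ICD-9 196--198)
#'
#' @return named list of ICD-9 code prefixes per site label.
#' @export
default_metastasis_map <- function() {
  list(
    lung = "197.0",
    liver = "197.7",
    bone_or_marrow = "198.5",
    brain_or_spinal_cord = c("198.3", "198.4"),
    adrenal = "198.7"
  )
}

# required columns per table, in file order
emr_schemas <- list(
  patients = c("patient_id", "birth_date", "sex"),
  diagnoses = c("patient_id", "date", "icd9"),
  drug_records = c("patient_id", "drug", "date", "days_supply", "kind"),
  lab_results = c("patient_id", "date", "analyte", "value", "uln")
)

lab_analytes <- c("ALT", "AST", "ALP", "BILI")

empty_emr_tables <- function() {
  list(
    patients = tibble(patient_id = character(), birth_date = as.Date(character()),
                      sex = character()),
    diagnoses = tibble(patient_id = character(), date = as.Date(character()),
                       icd9 = character()),
    drug_records = tibble(patient_id = character(), drug = character(),
                          date = as.Date(character()),
                          days_supply = integer(), kind = character()),
    lab_results = tibble(patient_id = character(), date = as.Date(character()),
                         analyte = character(), value = double(), uln = double())
  )
}

#' Construct an EMR dataset from its four component tables
#'
#' Normalizes column types (calendar dates, lowercase drug names), attaches
#' a provenance label, and validates. Validation is total: every malformed
#' row is reported with its table and row index; nothing is silently
#' dropped.
#'
#' @param patients,diagnoses,drug_records,lab_results data frames following
#'   the documented schemas.
#' @param provenance free-text label naming the data source.
#' @param validate run [validate_emr_dataset()] and error on any issue.
#' @return object of class `emr_dataset`: a list of the four tibbles plus
#'   `provenance` and the (empty, when valid) `validation` issue table.
#' @export
emr_dataset <- function(patients = NULL, diagnoses = NULL, drug_records = NULL,
                        lab_results = NULL, provenance = "unspecified",
                        validate = TRUE) {
  empty <- empty_emr_tables()
  tables <- list(patients = patients, diagnoses = diagnoses,
                 drug_records = drug_records, lab_results = lab_results)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.null(tab) || nrow(tab) == 0) {
      tables[[nm]] <- empty[[nm]]
      next
    }
    missing_cols <- setdiff(emr_schemas[[nm]], names(tab))
    if (length(missing_cols)) {
      abort(sprintf("schema error: missing column %s.%s", nm, missing_cols[1]),
            class = "hepatosafe_schema_error")
    }
    tables[[nm]] <- as_tibble(tab)[emr_schemas[[nm]]]
  }
  tables$patients$birth_date <- as.Date(tables$patients$birth_date)
  tables$diagnoses$date <- as.Date(tables$diagnoses$date)
  tables$drug_records$date <- as.Date(tables$drug_records$date)
  tables$drug_records$drug <- tolower(tables$drug_records$drug)
  tables$drug_records$days_supply <- as.integer(tables$drug_records$days_supply)
  tables$lab_results$date <- as.Date(tables$lab_results$date)
  tables$lab_results$value <- as.double(tables$lab_results$value)
  tables$lab_results$uln <- as.double(tables$lab_results$uln)

  ds <- structure(c(tables, list(provenance = provenance,
                                 validation = NULL)),
                  class = "emr_dataset")
  ds$validation <- validate_emr_dataset(ds)
  if (validate && nrow(ds$validation) > 0) {
    msgs <- sprintf("%s row %d: %s", ds$validation$table, ds$validation$row,
                    ds$validation$problem)
    abort(paste0("invalid EMR dataset:\n",
                 paste(" -", head(msgs, 20), collapse = "\n")),
          class = "hepatosafe_validation_error")
  }
  ds
}

#' Validate an EMR dataset
#'
#' Checks every declared invariant of the relational model: unique patient
#' ids, parseable dates, birth dates preceding all of a patient's record
#' dates, ICD-9 code syntax, positive days supply, known record kinds and
#' analytes, non-negative lab values with a strictly positive ULN, and
#' foreign-key resolution of every `patient_id`.
#'
#' @param dataset an `emr_dataset` (or compatible list of tables).
#' @return tibble of issues with columns `table`, `row`, `problem`; zero
#'   rows when the dataset is valid.
#' @export
validate_emr_dataset <- function(dataset) {
  issues <- list()
  note <- function(table, rows, problem) {
    if (length(rows)) {
      issues[[length(issues) + 1]] <<- tibble(table = table,
                                              row = as.integer(rows),
                                              problem = problem)
    }
  }
  pat <- dataset$patients
  dup <- which(duplicated(pat$patient_id))
  note("patients", dup, "duplicate patient_id")
  note("patients", which(is.na(pat$birth_date)), "unparseable birth_date")
  note("patients", which(!pat$sex %in% c("male", "female", "unknown")),
       "sex must be male, female or unknown")

  known <- pat$patient_id
  icd9_ok <- function(x) {
    grepl("^\\d{3}(\\.\\d{1,2})?$", x) | grepl("^V\\d{2}(\\.\\d{1,2})?$", x) |
      grepl("^E\\d{3}(\\.\\d)?$", x)
  }
  dx <- dataset$diagnoses
  note("diagnoses", which(is.na(dx$date)), "unparseable date")
  note("diagnoses", which(!icd9_ok(dx$icd9)), "malformed ICD-9 code")
  note("diagnoses", which(!dx$patient_id %in% known), "unknown patient_id")

  dr <- dataset$drug_records
  note("drug_records", which(is.na(dr$date)), "unparseable date")
  note("drug_records", which(!is.na(dr$days_supply) & dr$days_supply < 1),
       "days_supply must be >= 1 when present")
  note("drug_records", which(!dr$kind %in% c("prescription", "administration")),
       "kind must be prescription or administration")
  note("drug_records", which(!dr$patient_id %in% known), "unknown patient_id")

  lab <- dataset$lab_results
  note("lab_results", which(is.na(lab$date)), "unparseable date")
  note("lab_results", which(!lab$analyte %in% lab_analytes),
       "analyte must be one of ALT, AST, ALP, BILI")
  note("lab_results", which(is.na(lab$value) | lab$value < 0),
       "value must be a non-negative number")
  note("lab_results", which(is.na(lab$uln) | lab$uln <= 0),
       "uln must be > 0")
  note("lab_results", which(!lab$patient_id %in% known), "unknown patient_id")

  # birth precedes all record dates for that patient
  birth <- setNames(pat$birth_date, pat$patient_id)
  for (nm in c("diagnoses", "drug_records", "lab_results")) {
    tab <- dataset[[nm]]
    ok_id <- tab$patient_id %in% known
    bad <- which(ok_id & !is.na(tab$date) &
                   tab$date <= birth[tab$patient_id])
    note(nm, bad, "record date not after patient birth_date")
  }

  if (length(issues)) bind_rows(issues) else {
    tibble(table = character(), row = integer(), problem = character())
  }
}

#' Read an EMR dataset from CSV files
#'
#' Expects four UTF-8, comma-delimited files with header rows following the
#' schemas `patients(patient_id,birth_date,sex)`,
#' `diagnoses(patient_id,date,icd9)`,
#' `drug_records(patient_id,drug,date,days_supply,kind)` and
#' `lab_results(patient_id,date,analyte,value,uln)`. Dates are ISO-8601; an
#' empty `days_supply` field means absent.
#'
#' @param paths either a directory containing `patients.csv`,
#'   `diagnoses.csv`, `drug_records.csv`, `lab_results.csv`, or a named list
#'   of the four file paths.
#' @param config optional [study_config()]; currently only carried through.
#' @param provenance provenance label stored on the dataset.
#' @return validated `emr_dataset`.
#' @export
load_dataset <- function(paths, config = study_config(),
                         provenance = NULL) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    dirp <- paths
    paths <- lapply(setNames(nm = names(emr_schemas)), function(nm) {
      file.path(dirp, paste0(nm, ".csv"))
    })
    if (is.null(provenance)) provenance <- basename(dirp)
  }
  stopifnot(all(names(emr_schemas) %in% names(paths)))
  if (is.null(provenance)) provenance <- "csv"
  col_specs <- list(
    patients = readr::cols(patient_id = "c", birth_date = readr::col_date(),
                           sex = "c"),
    diagnoses = readr::cols(patient_id = "c", date = readr::col_date(),
                            icd9 = "c"),
    drug_records = readr::cols(patient_id = "c", drug = "c",
                               date = readr::col_date(),
                               days_supply = "i", kind = "c"),
    lab_results = readr::cols(patient_id = "c", date = readr::col_date(),
                              analyte = "c", value = "d", uln = "d")
  )
  tabs <- list()
  for (nm in names(emr_schemas)) {
    path <- paths[[nm]]
    if (!file.exists(path)) {
      abort(sprintf("cannot read %s table: no file at %s", nm, path))
    }
    header <- names(readr::read_csv(path, n_max = 0, col_types =
                                      readr::cols(.default = "c"),
                                    show_col_types = FALSE))
    missing_cols <- setdiff(emr_schemas[[nm]], header)
    if (length(missing_cols)) {
      abort(sprintf("schema error: missing column %s.%s", nm, missing_cols[1]),
            class = "hepatosafe_schema_error")
    }
    tabs[[nm]] <- readr::read_csv(path, col_types = col_specs[[nm]],
                                  na = "", progress = FALSE,
                                  show_col_types = FALSE)
  }
  emr_dataset(tabs$patients, tabs$diagnoses, tabs$drug_records,
              tabs$lab_results, provenance = provenance)
}

#' Write an EMR dataset to CSV files
#'
#' Writes the four tables as UTF-8 CSVs with ISO-8601 dates into
#' `directory`; absent `days_supply` is written as an empty field. A write
#' followed by [load_dataset()] reproduces the dataset field-for-field.
#'
#' @param dataset an `emr_dataset`.
#' @param directory output directory (created if needed).
#' @return (invisibly) named vector of the four file paths.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "emr_dataset"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory %s", directory))
  }
  out <- c()
  for (nm in names(emr_schemas)) {
    path <- file.path(directory, paste0(nm, ".csv"))
    readr::write_csv(dataset[[nm]], path, na = "")
    out[nm] <- path
  }
  invisible(out)
}

#' @export
print.emr_dataset <- function(x, ...) {
  cat(sprintf("<emr_dataset: %s>\n", x$provenance))
  for (nm in names(emr_schemas)) {
    cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
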