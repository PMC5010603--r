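#' Baseline characteristics table
#'
#' Per-drug cohort summary: cohort size, age (mean, SD), male gender,
#' metastasis sites, and line of treatment in the strata first / second /
#' third or higher. Percentages are rounded half-up to one decimal.
#'
#' @param cohort output of [select_new_users()].
#' @param config a [study_config()].
#' @return tibble (`drug`, `characteristic`, `n`, `pct`, `mean`, `sd`).
#' @export
build_baseline_table <- function(cohort, config = study_config()) {
  drugs <- config$study_drugs$drug[config$study_drugs$anti_vegf]
  sites <- c(names(config$metastasis_code_map), "other", "none")
  rows <- list()
  for (drug_i in drugs) {
    d <- cohort[cohort$drug == drug_i, ]
    n <- nrow(d)
    pct <- function(k) if (n == 0) NA_real_ else round_half_up(100 * k / n, 1)
    add <- function(characteristic, k = NA_integer_, p = NA_real_,
                    m = NA_real_, s = NA_real_) {
      rows[[length(rows) + 1]] <<- tibble(
        drug = drug_i, characteristic = characteristic,
        n = as.integer(k), pct = p, mean = m, sd = s)
    }
    add("cohort_size", n)
    add("age", m = if (n) mean(d$age_at_start) else NA_real_,
        s = if (n > 1) stats::sd(d$age_at_start) else NA_real_)
    k_male <- sum(d$sex == "male")
    add("male", k_male, pct(k_male))
    for (site in sites) {
      k <- sum(vapply(d$metastasis_sites, function(s) site %in% s,
                      logical(1)))
      add(paste0("metastasis_", site), k, pct(k))
    }
    k1 <- sum(d$line_of_therapy == 1)
    k2 <- sum(d$line_of_therapy == 2)
    k3 <- sum(d$line_of_therapy >= 3)
    add("line_first", k1, pct(k1))
    add("line_second", k2, pct(k2))
    add("line_third_plus", k3, pct(k3))
  }
  bind_rows(rows)
}

#' Run the full surveillance study
#'
#' Orchestrates every stage: cohort selection with exclusion accounting,
#' treatment-episode construction, outcome classification (LC thresholds,
#' Hy's law, DILI screen), incidence estimation and time-to-event
#' summaries. Deterministic for fixed inputs; per-stage row counts are
#' collected in the report's `log`.
#'
#' @param dataset an `emr_dataset`, or `NULL` to read from `paths`.
#' @param config a [study_config()].
#' @param paths passed to [load_dataset()] when `dataset` is `NULL`.
#' @param database_label data source label on output tables (defaults to
#'   the dataset provenance).
#' @param adjudications optional tibble of externally adjudicated DILI
#'   determinations (`patient_id`, `dili_confirmed`), joined onto the
#'   screen flags; the pipeline never computes this verdict itself.
#' @return object of class `study_report`: a list with `cohort`,
#'   `exclusions`, `episodes`, `eligibility`, `events`, `dili_flags`,
#'   `incidence`, `time_to_event`, `baseline`, `log`, `meta`.
#' @export
run_study <- function(dataset = NULL, config = study_config(), paths = NULL,
                      database_label = NULL, adjudications = NULL) {
  if (is.null(dataset)) {
    if (is.null(paths)) abort("either dataset or paths must be supplied")
    dataset <- load_dataset(paths, config)
  }
  stopifnot(inherits(dataset, "emr_dataset"))
  if (is.null(database_label)) database_label <- dataset$provenance

  cohort <- select_new_users(dataset, config)
  exclusions <- attr(cohort, "exclusions")
  episodes <- build_patient_episodes(dataset, cohort, config)
  catalog <- threshold_catalog()
  outcomes <- analyze_outcomes(dataset, cohort, episodes, config, catalog)
  incidence <- build_incidence_table(cohort, episodes, outcomes, config,
                                     catalog, database_label)
  tte <- build_time_to_event_table(outcomes, config)
  baseline <- build_baseline_table(cohort, config)

  dili_flags <- outcomes$dili_flags
  if (!is.null(adjudications)) {
    dili_flags <- left_join(dili_flags,
                            adjudications[c("patient_id", "dili_confirmed")],
                            by = "patient_id")
  }

  n_candidates <- nrow(cohort) + nrow(exclusions)
  log <- tibble(
    stage = c("candidates", "cohort", "excluded", "episodes", "events",
              "dili_flags"),
    rows = c(n_candidates, nrow(cohort), nrow(exclusions), nrow(episodes),
             nrow(outcomes$events), nrow(dili_flags))
  )
  meta <- list(database_label = database_label,
               config_hash = rlang::hash(config),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("hepatosafe")))

  structure(list(cohort = cohort, exclusions = exclusions,
                 episodes = episodes, eligibility = outcomes$eligibility,
                 events = outcomes$events, dili_flags = dili_flags,
                 incidence = incidence, time_to_event = tte,
                 baseline = baseline, log = log, meta = meta),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %s>\n", x$meta$database_label))
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("  %-10s %6d rows\n", x$log$stage[i], x$log$rows[i]))
  }
  invisible(x)
}

# "4.6 (1.9, 9.3)"-style cell; zero-case cells carry the one-sided upper
# bound as "0 (0, x)"; undefined cells render as NA
format_stat_cell <- function(point, lo, hi) {
  if (is.na(point)) return("NA")
  sprintf("%s (%s, %s)", format(point), format(lo), format(hi))
}

write_markdown_table <- function(df, path, title) {
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  cells[is.na(df)] <- "NA"
  lines <- c(paste0("## ", title), "",
             paste0("| ", paste(names(df), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
             apply(cells, 1, function(r) {
               paste0("| ", paste(r, collapse = " | "), " |")
             }))
  writeLines(lines, path)
}

#' Render report tables to files
#'
#' Writes the baseline, incidence, time-to-event, DILI-flag and exclusion
#' tables. `csv` output is re-parseable; `markdown` renders compact cells
#' such as `4.6 (1.9, 9.3)`, one-sided `0 (0, x)` bounds for zero-case
#' cells, and `NA` for empty time-to-event summaries, with category rows in
#' catalog order.
#'
#' @param report a `study_report`.
#' @param directory output directory (created if needed).
#' @param format `"csv"` or `"markdown"`.
#' @return (invisibly) character vector of the files written.
#' @export
render_tables <- function(report, directory, format = c("csv", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  }
  ext <- if (format == "csv") ".csv" else ".md"
  out <- c()
  emit <- function(df, name, title) {
    path <- file.path(directory, paste0(name, ext))
    if (format == "csv") readr::write_csv(df, path, na = "NA")
    else write_markdown_table(df, path, title)
    out <<- c(out, path)
  }

  cohort_flat <- report$cohort |>
    mutate(metastasis_sites = vapply(.data$metastasis_sites, paste,
                                     character(1), collapse = ";"),
           concomitant_meds = vapply(.data$concomitant_meds, paste,
                                     character(1), collapse = ";"))
  emit(cohort_flat, "cohort", "Cohort entries")
  emit(report$exclusions, "exclusions", "Exclusions")
  emit(report$baseline, "baseline", "Baseline characteristics")
  if (format == "csv") {
    emit(report$incidence, "incidence", "Incidence of LC elevations")
  } else {
    compact <- report$incidence |>
      mutate(
        cases = sprintf("%d/%d", .data$n_cases, .data$n_evaluated),
        cum_inc = purrr::pmap_chr(
          list(.data$cum_inc_pct, .data$cum_inc_lo, .data$cum_inc_hi),
          format_stat_cell),
        ir = purrr::pmap_chr(
          list(.data$rate_per_100py, .data$rate_lo, .data$rate_hi),
          format_stat_cell)
      ) |>
      select("database", "drug", "category", "stratum", "cases",
             "cum_inc", "ir")
    emit(compact, "incidence", "Incidence of LC elevations")
  }
  emit(report$time_to_event, "time_to_event", "Time to event")
  emit(report$dili_flags, "dili_flags", "Potential DILI screen flags")
  emit(report$log, "run_log", "Stage log")
  invisible(out)
}
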