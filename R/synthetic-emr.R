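#' Simulation configuration for the synthetic EMR generator
#'
#' Describes the data-generating process the analysis assumes: accrual of
#' new users per drug, prescription refill patterns with occasional long
#' gaps, a periodic lab measurement schedule, log-normal baseline lab
#' levels (median around 0.6x ULN), and constant per-drug, per-analyte
#' hazards of a threshold-crossing LC elevation while exposed. Elevation
#' times are drawn in exposed time and realized at the next scheduled lab
#' date, so sparse lab schedules miss transient elevations the way
#' real-world monitoring does.
#'
#' @param n_patients named integer vector of cohort sizes per drug.
#' @param accrual_start,accrual_end accrual window for drug start dates.
#' @param n_refills_mean mean number of refill prescriptions after the
#'   first (Poisson).
#' @param refill_gap_extra_mean,refill_gap_extra_sd normal draw (truncated
#'   at 0, rounded) for extra days between one prescription's nominal
#'   coverage end and the next prescription.
#' @param long_gap_probability probability a refill gap is instead
#'   `long_gap_extra_days` (a coverage gap exceeding the 30-day allowance
#'   splits the course into two episodes).
#' @param long_gap_extra_days length of such a long coverage gap.
#' @param days_supply_days fixed recorded days supply per prescription, or
#'   `NA` to leave it absent so the imputed duration applies.
#' @param lab_interval_days days between scheduled follow-up lab panels.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   non-elevated lab level as a multiple of ULN.
#' @param noise_cap_multiple cap (xULN) on non-elevated draws; below 2 so
#'   that with all hazards zero no follow-up result reaches 2x ULN.
#' @param elevation_hazard named list per drug of named per-analyte
#'   constant hazards (events per person-year while exposed).
#' @param elevation_multiple named per-analyte threshold multiple the
#'   realized elevation crosses.
#' @param hys_law_fraction fraction of realized ALT elevations accompanied
#'   same-day by bilirubin >=2x and ALP <2x ULN.
#' @param switch_probability probability of starting an alternate anti-VEGF
#'   drug after the index course ends.
#' @param prior_line_probability probability of a prior (non-anti-VEGF)
#'   systemic regimen, making the index drug second line.
#' @param dili_code_rate hazard (per person-year over the exposure span
#'   plus 90 days) of a potential-DILI ICD-9 code.
#' @param missing_baseline_probability probability the baseline bilirubin
#'   is deliberately suppressed (to exercise the exclusion path).
#' @param uln named lab-unit upper limits of normal per analyte.
#' @param seed integer; the global seed derives one RNG substream per
#'   patient, so configurations differing only in the lab schedule share
#'   identical patient histories and true event times (common random
#'   numbers).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = c(pazopanib = 50, sorafenib = 30,
                                             sunitinib = 80, bevacizumab = 25),
                              accrual_start = as.Date("2009-10-01"),
                              accrual_end = as.Date("2013-02-17"),
                              n_refills_mean = 5,
                              refill_gap_extra_mean = 2,
                              refill_gap_extra_sd = 6,
                              long_gap_probability = 0.08,
                              long_gap_extra_days = 45,
                              days_supply_days = NA_integer_,
                              lab_interval_days = 30,
                              baseline_meanlog = log(0.6),
                              baseline_sdlog = 0.3,
                              noise_cap_multiple = 1.95,
                              elevation_hazard = list(
                                pazopanib = c(ALT = 0.25, BILI = 0.08),
                                sorafenib = c(ALT = 0.15, BILI = 0.10),
                                sunitinib = c(ALT = 0.12, BILI = 0.10),
                                bevacizumab = c(ALT = 0.15, BILI = 0.05)),
                              elevation_multiple = c(ALT = 3, AST = 3,
                                                     ALP = 2, BILI = 2),
                              hys_law_fraction = 0.01,
                              switch_probability = 0.10,
                              prior_line_probability = 0.30,
                              dili_code_rate = 0.02,
                              missing_baseline_probability = 0,
                              uln = c(ALT = 40, AST = 40, ALP = 120,
                                      BILI = 1.2),
                              seed = 1L) {
  hazards <- unlist(elevation_hazard)
  if (length(hazards) && any(hazards < 0)) {
    abort("elevation hazards must be >= 0", class = "hepatosafe_config_error")
  }
  probs <- c(long_gap_probability, hys_law_fraction, switch_probability,
             prior_line_probability, missing_baseline_probability)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]",
          class = "hepatosafe_config_error")
  }
  if (dili_code_rate < 0) {
    abort("dili_code_rate must be >= 0", class = "hepatosafe_config_error")
  }
  structure(list(
    n_patients = n_patients,
    accrual_start = as.Date(accrual_start),
    accrual_end = as.Date(accrual_end),
    n_refills_mean = n_refills_mean,
    refill_gap_extra_mean = refill_gap_extra_mean,
    refill_gap_extra_sd = refill_gap_extra_sd,
    long_gap_probability = long_gap_probability,
    long_gap_extra_days = long_gap_extra_days,
    days_supply_days = days_supply_days,
    lab_interval_days = lab_interval_days,
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    noise_cap_multiple = noise_cap_multiple,
    elevation_hazard = elevation_hazard,
    elevation_multiple = elevation_multiple,
    hys_law_fraction = hys_law_fraction,
    switch_probability = switch_probability,
    prior_line_probability = prior_line_probability,
    dili_code_rate = dili_code_rate,
    missing_baseline_probability = missing_baseline_probability,
    uln = uln,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys mirror the [simulation_config()]
#'   arguments (unknown keys are an error).
#' @return `simulation_config`.
#' @export
simulation_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("unknown simulation config keys: %s",
                  paste(unknown, collapse = ", ")),
          class = "hepatosafe_config_error")
  }
  for (nm in c("n_patients", "elevation_multiple", "uln")) {
    if (nm %in% names(vals)) vals[[nm]] <- unlist(vals[[nm]])
  }
  if ("elevation_hazard" %in% names(vals)) {
    vals$elevation_hazard <- lapply(vals$elevation_hazard, unlist)
  }
  do.call(simulation_config, vals)
}

# merge sorted inclusive day intervals allowing gaps <= gap_days; plain
# numeric version used internally by the generator
merge_day_intervals <- function(starts, ends, gap_days = 30) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - me - 1 <= gap_days) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

# map an exposed-day index (1-based within the union of episodes) to a
# calendar day offset
exposed_day_to_offset <- function(day_index, ep_start, ep_end) {
  lens <- ep_end - ep_start + 1
  cum <- cumsum(lens)
  j <- which(day_index <= cum)[1]
  prior <- if (j == 1) 0 else cum[j - 1]
  ep_start[j] + (day_index - prior - 1)
}

#' Generate a synthetic EMR dataset
#'
#' Draws one patient history at a time from the configured data-generating
#' process: an RCC diagnosis before the first anti-VEGF record, baseline
#' ALT/AST/ALP/bilirubin panels inside the baseline window (so cohort
#' eligibility is guaranteed by construction unless deliberately
#' suppressed), prescriptions with refill gaps from the configured pattern,
#' scheduled follow-up lab panels, and exponential threshold-crossing times
#' while exposed, realized at the next scheduled lab date at or after the
#' event time. Deterministic for a fixed seed.
#'
#' @param sim a [simulation_config()].
#' @return validated `emr_dataset`.
#' @export
generate_dataset <- function(sim = simulation_config()) {
  stopifnot(inherits(sim, "simulation_config"))
  set.seed(sim$seed)
  rules <- default_study_drugs()
  imputed <- setNames(rules$imputed_duration_days, rules$drug)
  kinds <- setNames(rules$kind, rules$drug)
  analytes <- c("ALT", "AST", "ALP", "BILI")

  patients <- list(); diagnoses <- list(); drugs <- list(); labs <- list()
  accrual_span <- as.integer(sim$accrual_end - sim$accrual_start)
  idx <- 0L

  # one RNG substream per patient, seeded from the global seed; every
  # schedule-independent quantity (demographics, prescriptions, true
  # elevation times and values) is drawn before the lab-noise draws, so
  # two runs differing only in the lab schedule share identical patient
  # histories and true event times (common random numbers)
  total_n <- sum(sim$n_patients)
  patient_seeds <- if (total_n > 0) {
    sample.int(.Machine$integer.max, total_n)
  } else integer(0)

  for (drug_i in names(sim$n_patients)) {
    n <- sim$n_patients[[drug_i]]
    if (n == 0) next
    dur <- if (!is.na(sim$days_supply_days)) sim$days_supply_days
           else imputed[[drug_i]]
    hazards <- sim$elevation_hazard[[drug_i]]
    hazard_analytes <- sort(names(hazards)[hazards > 0])
    for (j in seq_len(n)) {
      idx <- idx + 1L
      pid <- sprintf("S%05d", idx)
      set.seed(patient_seeds[idx])
      start <- sim$accrual_start + floor(runif(1, 0, accrual_span + 1))
      age <- runif(1, 40, 85)
      birth <- start - round(age * 365.25)
      sex <- if (runif(1) < 0.85) "male" else "female"
      patients[[idx]] <- data.frame(patient_id = pid, birth_date = birth,
                                    sex = sex)
      dx_dates <- start - sample(30:400, 1)
      dx_codes <- sample(c("189.0", "189.1"), 1)
      if (runif(1) < 0.30) {
        dx_dates <- c(dx_dates, start - sample(10:200, 1))
        dx_codes <- c(dx_codes, "197.0")
      }
      if (runif(1) < 0.15) {
        dx_dates <- c(dx_dates, start - sample(10:200, 1))
        dx_codes <- c(dx_codes, "198.5")
      }

      drug_rows <- list()
      if (runif(1) < sim$prior_line_probability) {
        prior_start <- start - sample(150:300, 1)
        drug_rows[[1]] <- data.frame(
          patient_id = pid, drug = "interferon",
          date = prior_start + c(0, 30, 60),
          days_supply = NA_integer_, kind = "prescription")
      }

      n_presc <- 1L + rpois(1, sim$n_refills_mean)
      extras <- pmax(0, round(rnorm(n_presc - 1, sim$refill_gap_extra_mean,
                                    sim$refill_gap_extra_sd)))
      long <- runif(max(n_presc - 1, 0)) < sim$long_gap_probability
      extras[long] <- sim$long_gap_extra_days
      offsets <- cumsum(c(0, dur + extras))
      rx_dates <- start + offsets
      drug_rows[[length(drug_rows) + 1]] <- data.frame(
        patient_id = pid, drug = drug_i, date = rx_dates,
        days_supply = if (is.na(sim$days_supply_days)) NA_integer_
                      else as.integer(sim$days_supply_days),
        kind = kinds[[drug_i]])

      eps <- merge_day_intervals(offsets, offsets + dur - 1)
      exposure_days <- sum(eps$end - eps$start + 1)
      last_end <- start + max(eps$end)

      if (runif(1) < sim$switch_probability) {
        alt_drug <- sample(setdiff(rules$drug, drug_i), 1)
        alt_start <- last_end + sample(5:40, 1)
        drug_rows[[length(drug_rows) + 1]] <- data.frame(
          patient_id = pid, drug = alt_drug, date = alt_start,
          days_supply = NA_integer_, kind = kinds[[alt_drug]])
      }
      drugs[[idx]] <- do.call(rbind, drug_rows)

      # baseline panel inside [start - 30, start]
      base_date <- start - sample(0:20, 1)
      base_analytes <- analytes
      if (runif(1) < sim$missing_baseline_probability) {
        base_analytes <- setdiff(base_analytes, "BILI")
      }
      base_mult <- pmin(rlnorm(length(base_analytes), sim$baseline_meanlog,
                               sim$baseline_sdlog), sim$noise_cap_multiple)
      lab_rows <- list(data.frame(
        patient_id = pid, date = base_date, analyte = base_analytes,
        value = base_mult * sim$uln[base_analytes],
        uln = unname(sim$uln[base_analytes])))

      # true elevation times (exponential in exposed days) and the values
      # they will take when realized at a lab; drawn before any
      # schedule-dependent noise
      event_time <- setNames(rep(Inf, length(hazard_analytes)),
                             hazard_analytes)
      event_mult <- setNames(rep(NA_real_, length(hazard_analytes)),
                             hazard_analytes)
      for (an in hazard_analytes) {
        event_time[an] <- rexp(1, hazards[[an]] / 365.25)
        event_mult[an] <- sim$elevation_multiple[[an]] * (1 + rexp(1, 3))
      }
      hys_draw <- runif(1)
      hys_bili <- 2 * (1 + rexp(1, 4))
      hys_alp <- runif(1, 0.8, 1.5)

      if (sim$dili_code_rate > 0) {
        span_days <- as.integer(last_end - start) + 90
        t_dili <- rexp(1, sim$dili_code_rate / 365.25)
        if (t_dili <= span_days) {
          dx_dates <- c(dx_dates, start + ceiling(t_dili))
          dx_codes <- c(dx_codes, sample(c("570.2", "573.3", "782.4"), 1))
        }
      }
      diagnoses[[idx]] <- data.frame(patient_id = pid, date = dx_dates,
                                     icd9 = dx_codes)

      # scheduled follow-up panels through the end of exposure; elevation
      # events are realized at the next scheduled lab at or after the
      # event time (later labs may therefore miss short-lived elevations)
      sched <- if (max(eps$end) >= sim$lab_interval_days) {
        seq(sim$lab_interval_days, max(eps$end), by = sim$lab_interval_days)
      } else integer(0)
      if (length(sched)) {
        lab_dates <- start + sched
        mult <- matrix(pmin(rlnorm(length(sched) * length(analytes),
                                   sim$baseline_meanlog, sim$baseline_sdlog),
                            sim$noise_cap_multiple),
                       nrow = length(sched))
        colnames(mult) <- analytes

        alt_event_row <- NA_integer_
        for (an in hazard_analytes) {
          if (event_time[an] > exposure_days) next
          ev_offset <- exposed_day_to_offset(ceiling(event_time[an]),
                                             eps$start, eps$end)
          k <- which(sched >= ev_offset)
          if (length(k) == 0) next  # missed: no later scheduled lab
          mult[k[1], an] <- event_mult[an]
          if (an == "ALT") alt_event_row <- k[1]
        }
        if (!is.na(alt_event_row) && hys_draw < sim$hys_law_fraction) {
          mult[alt_event_row, "BILI"] <- hys_bili
          mult[alt_event_row, "ALP"] <- hys_alp
        }
        lab_rows[[2]] <- data.frame(
          patient_id = pid,
          date = rep(lab_dates, times = length(analytes)),
          analyte = rep(analytes, each = length(sched)),
          value = as.vector(mult) * rep(sim$uln[analytes],
                                        each = length(sched)),
          uln = rep(unname(sim$uln[analytes]), each = length(sched)))
      }
      labs[[idx]] <- do.call(rbind, lab_rows)
    }
  }

  emr_dataset(
    patients = if (length(patients)) bind_rows(patients) else NULL,
    diagnoses = if (length(diagnoses)) bind_rows(diagnoses) else NULL,
    drug_records = if (length(drugs)) bind_rows(drugs) else NULL,
    lab_results = if (length(labs)) bind_rows(labs) else NULL,
    provenance = sprintf("synthetic (seed %d)", sim$seed)
  )
}
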