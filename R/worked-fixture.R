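#' Handcrafted worked fixture dataset
#'
#' A deterministic ~20-patient dataset exercising every boundary the
#' pipeline must get right: a refill gap of exactly 30 days (one episode)
#' and of 31 days (two episodes), truncation by an alternate anti-VEGF
#' drug, a baseline ALT of exactly 3.0x ULN (partial category
#' eligibility), a same-day Hy's-law triple plus an ALP = 2.0x near-miss,
#' a potential-DILI ICD-9 code inside the screening window and another 91
#' days past the last exposure date (outside), and one excluded patient
#' per exclusion reason. No randomness is involved.
#'
#' @return validated `emr_dataset`.
#' @export
generate_worked_fixture <- function() {
  o <- as.Date("2010-06-01")        # common start-date origin
  uln <- c(ALT = 40, AST = 40, ALP = 120, BILI = 1.2)

  patients <- list(); diagnoses <- list(); drugs <- list(); labs <- list()
  add <- function(store, ...) {
    store[[length(store) + 1]] <- data.frame(...)
    store
  }
  # routine scaffolding shared by most patients: RCC code before start and
  # a normal baseline panel 10 days before start
  scaffold <- function(pid, start, birth = as.Date("1950-03-15"),
                       sex = "male", rcc = TRUE) {
    patients <<- add(patients, patient_id = pid, birth_date = birth,
                     sex = sex)
    if (rcc) {
      diagnoses <<- add(diagnoses, patient_id = pid, date = start - 60,
                        icd9 = "189.0")
    }
    labs <<- add(labs, patient_id = pid, date = start - 10,
                 analyte = c("ALT", "AST", "ALP", "BILI"),
                 value = c(0.6, 0.6, 0.7, 0.5) *
                   uln[c("ALT", "AST", "ALP", "BILI")],
                 uln = unname(uln[c("ALT", "AST", "ALP", "BILI")]))
  }
  rx <- function(pid, drug, dates, kind = "prescription") {
    drugs <<- add(drugs, patient_id = pid, drug = drug, date = dates,
                  days_supply = NA_integer_, kind = kind)
  }
  lab <- function(pid, date, analyte, multiple) {
    labs <<- add(labs, patient_id = pid, date = date, analyte = analyte,
                 value = multiple * unname(uln[analyte]),
                 uln = unname(uln[analyte]))
  }

  # W01 pazopanib: coverage gap exactly 30 days -> one episode [0, 89]
  scaffold("W01", o); rx("W01", "pazopanib", o + c(0, 60))
  # W02 pazopanib: coverage gap 31 days -> two episodes
  scaffold("W02", o); rx("W02", "pazopanib", o + c(0, 61))
  # W03 pazopanib truncated by sunitinib starting day 15; the sunitinib
  # entry itself is excluded as concurrent use
  scaffold("W03", o); rx("W03", "pazopanib", o)
  rx("W03", "sunitinib", o + 15)
  lab("W03", o + 14, "ALT", 0.7)   # sunitinib baseline labs exist too
  # W04 pazopanib: baseline ALT exactly 3.0x ULN; follow-up ALT 3.5x day 30
  scaffold("W04", o)
  lab("W04", o - 5, "ALT", 3.0)
  rx("W04", "pazopanib", o + c(0, 30))
  lab("W04", o + 30, "ALT", 3.5)
  # W05 sorafenib: same-day Hy's-law triple on day 40
  scaffold("W05", o, sex = "female"); rx("W05", "sorafenib", o + c(0, 30))
  lab("W05", o + 40, "ALT", 3.5)
  lab("W05", o + 40, "BILI", 2.2)
  lab("W05", o + 40, "ALP", 1.5)
  # W06 sunitinib: triple with ALP exactly 2.0x -> Hy's law rejected (the
  # lab pair still screens as potential DILI)
  scaffold("W06", o); rx("W06", "sunitinib", o + c(0, 28))
  lab("W06", o + 30, "ALT", 3.5)
  lab("W06", o + 30, "BILI", 2.2)
  lab("W06", o + 30, "ALP", 2.0)
  # W07 sunitinib: DILI code 570.2 inside the span (day 10) and 573.3 at
  # 91 days past the last exposure date (outside the 90-day extension)
  scaffold("W07", o); rx("W07", "sunitinib", o)
  diagnoses <- add(diagnoses, patient_id = "W07", date = o + 10,
                   icd9 = "570.2")
  diagnoses <- add(diagnoses, patient_id = "W07", date = o + 27 + 91,
                   icd9 = "573.3")
  # W08 bevacizumab: administrations every 14 days -> one episode [0, 41];
  # BILI 1.2x on day 20 (a >1x event only)
  scaffold("W08", o, sex = "female")
  rx("W08", "bevacizumab", o + c(0, 14, 28), kind = "administration")
  lab("W08", o + 20, "BILI", 1.2)
  # W09 sorafenib, second line after an interferon course
  scaffold("W09", o); rx("W09", "sorafenib", o)
  rx("W09", "interferon", o - c(200, 170, 140))
  # W10 bevacizumab: ALT 8.5x on day 14
  scaffold("W10", o)
  rx("W10", "bevacizumab", o + c(0, 14), kind = "administration")
  lab("W10", o + 14, "ALT", 8.5)
  # W11-W14 routine users, one per drug, with metastasis codes and a
  # concomitant statin
  scaffold("W11", o)
  diagnoses <- add(diagnoses, patient_id = "W11", date = o - 30,
                   icd9 = "197.0")
  rx("W11", "pazopanib", o); rx("W11", "atorvastatin", o - 10)
  scaffold("W12", o, sex = "female")
  diagnoses <- add(diagnoses, patient_id = "W12", date = o - 30,
                   icd9 = "198.5")
  rx("W12", "sunitinib", o)
  scaffold("W13", o); rx("W13", "sorafenib", o)
  scaffold("W14", o)
  rx("W14", "bevacizumab", o + c(0, 14), kind = "administration")
  # W15 pazopanib: ALT 2.5x day 30 (>=2x event but no >=3x event)
  scaffold("W15", o); rx("W15", "pazopanib", o + c(0, 30))
  lab("W15", o + 30, "ALT", 2.5)
  # W16 sunitinib: BILI 2.5x day 40
  scaffold("W16", o); rx("W16", "sunitinib", o + c(0, 28))
  lab("W16", o + 40, "BILI", 2.5)
  # W17 pazopanib, age 17 at start -> excluded (age)
  scaffold("W17", o, birth = o - round(17.5 * 365.25))
  rx("W17", "pazopanib", o)
  # W18 sorafenib with no baseline bilirubin -> excluded
  patients <- add(patients, patient_id = "W18",
                  birth_date = as.Date("1950-03-15"), sex = "male")
  diagnoses <- add(diagnoses, patient_id = "W18", date = o - 60,
                   icd9 = "189.1")
  lab("W18", o - 10, "ALT", 0.6)
  rx("W18", "sorafenib", o)
  # W19 sunitinib started before the accrual window opens -> excluded
  scaffold("W19", as.Date("2009-06-01"))
  rx("W19", "sunitinib", as.Date("2009-06-01"))
  # W20 bevacizumab with no RCC diagnosis -> excluded
  scaffold("W20", o, rcc = FALSE)
  rx("W20", "bevacizumab", o + c(0, 14), kind = "administration")

  emr_dataset(patients = bind_rows(patients),
              diagnoses = bind_rows(diagnoses),
              drug_records = bind_rows(drugs),
              lab_results = bind_rows(labs),
              provenance = "worked fixture")
}
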