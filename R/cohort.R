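#' Cohort selection configuration
#'
#' Parameters of the new-user design: minimum age at index, washout length,
#' study window, follow-up length, the ICD-10 prefix lists for exclusions
#' and fracture history, the corticosteroid reimbursement threshold, and the
#' lookback window for exclusions and fracture history.
#'
#' @param min_age Minimum age (years) at the index date.
#' @param washout_months Months without any study-drug dispensing required
#'   before the index dispensation.
#' @param study_start,study_end Study window (ISO dates or `Date`).
#' @param followup_days Follow-up length after index.
#' @param exclusion_icd ICD-10 prefixes whose pre-index hospitalization
#'   excludes a patient (secondary osteoporosis proxies, GI events, ...).
#' @param fracture_icd ICD-10 prefixes defining osteoporotic fracture
#'   history.
#' @param corticosteroid_threshold Number of corticosteroid reimbursements
#'   in the lookback at or above which a patient is excluded.
#' @param lookback_months Lookback window (months before index) for the
#'   exclusion rules and fracture history.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(min_age = 50,
                          washout_months = 24,
                          study_start = "2009-01-01",
                          study_end = "2015-12-31",
                          followup_days = 365L,
                          exclusion_icd = default_exclusion_codes(),
                          fracture_icd = default_fracture_codes(),
                          corticosteroid_threshold = 3L,
                          lookback_months = 24) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(washout_months > 0, followup_days > 0, study_start < study_end)
  structure(list(
    min_age = min_age,
    washout_months = washout_months,
    washout_days = months_to_days(washout_months),
    study_start = study_start,
    study_end = study_end,
    followup_days = as.integer(followup_days),
    exclusion_icd = exclusion_icd,
    fracture_icd = fracture_icd,
    corticosteroid_threshold = as.integer(corticosteroid_threshold),
    lookback_months = lookback_months,
    lookback_days = months_to_days(lookback_months)
  ), class = "cohort_config")
}

new_attrition <- function(step, n_remaining) {
  rec <- data.frame(step = step, n_remaining = as.integer(n_remaining))
  rec$n_removed <- c(NA_integer_, -diff(rec$n_remaining))
  if (any(diff(rec$n_remaining) > 0)) {
    stop("attrition counts must be non-increasing", call. = FALSE)
  }
  structure(rec, class = c("attrition_record", "data.frame"))
}

append_attrition <- function(rec, step, n_remaining) {
  new_attrition(c(rec$step, step), c(rec$n_remaining, n_remaining))
}

#' @export
print.attrition_record <- function(x, ...) {
  cat("Cohort attrition\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

parse_claim_dates <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))
    stop("malformed date(s) in ", what, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  d
}

#' Identify new users of study drugs
#'
#' A patient's candidate index event is their first in-window study-drug
#' dispensation. The patient qualifies as a new user when no study-drug
#' dispensation occurs during the washout period before that date, the
#' observable history covers at least the washout, and the patient meets the
#' age criterion at index. Patients whose qualifying product is a
#' bisphosphonate--vitamin-D combination (`drug_class`
#' `"bisphosphonate_vitd"`) are not included, since the comparison requires
#' products with both brand and generic forms.
#'
#' @param dispensing Dispensing table with `patient_id`, `date`,
#'   `drug_class`, `molecule`, `brand`.
#' @param patients Patient table with `patient_id`, `age`,
#'   `observation_start` and the baseline covariates.
#' @param config A [cohort_config()].
#' @return A list: `index_events` (one row per retained patient with
#'   `index_date`, `molecule`, `group`, covariates) and `attrition`.
#' @export
identify_new_users <- function(dispensing, patients, config = cohort_config()) {
  disp <- as.data.table(dispensing)
  disp[, date := parse_claim_dates(date, "dispensing")]
  study <- disp[drug_class %in% c("bisphosphonate", "bisphosphonate_vitd")]
  setorder(study, patient_id, date, molecule, brand)

  inwin <- study[date >= config$study_start & date <= config$study_end]
  first <- inwin[, .SD[1L], by = patient_id]
  dup <- inwin[, .N, by = .(patient_id, date)][N > 1L]
  if (nrow(dup) && any(dup$date %in% first$index_date)) {
    warning("same-day multiple dispensations at index for some patients; ",
            "group taken from the first record under a deterministic sort")
  }
  setnames(first, "date", "index_date")
  rec <- new_attrition("in-window study-drug users", nrow(first))

  # washout: no study-drug dispensation in the washout_days before index
  prior <- study[first[, .(patient_id, index_date)], on = "patient_id",
                 nomatch = NULL][date < index_date &
                                   date >= index_date - config$washout_days]
  first <- first[!patient_id %in% unique(prior$patient_id)]
  rec <- append_attrition(rec, sprintf("washout %s months satisfied",
                                       config$washout_months), nrow(first))

  pat <- as.data.table(patients)
  first <- merge(first, pat, by = "patient_id", suffixes = c("", ".pat"))
  if ("observation_start" %in% names(first)) {
    first <- first[parse_claim_dates(observation_start, "patients") <=
                     index_date - config$washout_days]
  }
  rec <- append_attrition(rec, "observable history >= washout", nrow(first))

  first <- first[age >= config$min_age]
  rec <- append_attrition(rec, sprintf("age >= %s at index", config$min_age),
                          nrow(first))

  combo <- first$drug_class == "bisphosphonate_vitd"
  first <- first[!combo]
  rec <- append_attrition(rec, "not a vitamin-D combination initiator",
                          nrow(first))

  first[, group := ifelse(brand, "brand", "generic")]
  list(index_events = first[], attrition = rec)
}

#' Apply pre-index exclusion rules
#'
#' Removes candidates with at least `corticosteroid_threshold` corticosteroid
#' reimbursements in the lookback window, or any hospitalization whose
#' diagnosis matches a configured ICD prefix in that window. Counts removed
#' per rule are appended to the attrition record.
#'
#' @param candidates Output `index_events` of [identify_new_users()].
#' @param dispensing Full dispensing table (corticosteroid rows carry
#'   `drug_class == "corticosteroid"`).
#' @param hospitalizations Hospitalization table with `patient_id`,
#'   `admission_date`, `icd10`.
#' @param config A [cohort_config()].
#' @param attrition Attrition record to extend.
#' @return A list: filtered `index_events` and the extended `attrition`.
#' @export
apply_exclusions <- function(candidates, dispensing, hospitalizations,
                             config = cohort_config(),
                             attrition = NULL) {
  cand <- as.data.table(candidates)
  if (nrow(cand) == 0L) stop("empty candidate list", call. = FALSE)
  if (is.null(attrition)) attrition <- new_attrition("candidates", nrow(cand))

  disp <- as.data.table(dispensing)
  cort <- disp[drug_class == "corticosteroid"]
  if (nrow(cort)) {
    cort[, date := parse_claim_dates(date, "dispensing")]
    cort <- cort[cand[, .(patient_id, index_date)], on = "patient_id",
                 nomatch = NULL]
    cort <- cort[date < index_date & date >= index_date - config$lookback_days]
    ncort <- cort[, .N, by = patient_id]
    drop <- ncort$patient_id[ncort$N >= config$corticosteroid_threshold]
    cand <- cand[!patient_id %in% drop]
  }
  attrition <- append_attrition(
    attrition,
    sprintf("< %d corticosteroid reimbursements", config$corticosteroid_threshold),
    nrow(cand))

  hosp <- as.data.table(hospitalizations)
  if (nrow(hosp) && length(config$exclusion_icd)) {
    hosp[, admission_date := parse_claim_dates(admission_date, "hospitalizations")]
    hit <- hosp[icd_match(icd10, config$exclusion_icd)]
    hit <- hit[cand[, .(patient_id, index_date)], on = "patient_id",
               nomatch = NULL]
    hit <- hit[admission_date < index_date &
                 admission_date >= index_date - config$lookback_days]
    cand <- cand[!patient_id %in% unique(hit$patient_id)]
  }
  attrition <- append_attrition(attrition, "no exclusion-diagnosis hospitalization",
                                nrow(cand))
  list(index_events = cand[], attrition = attrition)
}

#' Detect and remove switchers
#'
#' Within the follow-up window after index, a patient is a *brand-generic
#' switcher* if a dispensation of the index molecule carries the opposite
#' brand flag, and a *molecule changer* if any study-drug dispensation is
#' for a different molecule. Both kinds are removed from the analysis
#' cohort; counts are returned separately per initiation group. Patients
#' with no post-index dispensation are retained (non-persistence is not
#' switching).
#'
#' @param index_events Index events (with `group`, `molecule`, `index_date`).
#' @param dispensing Dispensing table.
#' @param followup_days Follow-up window length in days.
#' @return A list: `cohort` (index events minus switchers), `switchers`
#'   (a data.frame of counts by group and kind).
#' @export
detect_switchers <- function(index_events, dispensing, followup_days = 365L) {
  ev <- as.data.table(index_events)
  disp <- as.data.table(dispensing)[drug_class == "bisphosphonate"]
  disp[, date := parse_claim_dates(date, "dispensing")]
  post <- disp[ev[, .(patient_id, index_date, index_mol = molecule,
                      index_brand = group == "brand")],
               on = "patient_id", nomatch = NULL]
  post <- post[date > index_date & date <= index_date + followup_days]
  post[, kind := fifelse(molecule != index_mol, "molecule",
                         fifelse(brand != index_brand, "brand_generic",
                                 "none"))]
  flagged <- post[kind != "none",
                  .(kind = kind[which.min(date)]), by = patient_id]
  ev[, switch_kind := "none"]
  ev[flagged, on = "patient_id", switch_kind := i.kind]
  counts <- as.data.frame(
    ev[, .(
      n_initiators = .N,
      n_brand_generic_switch = sum(switch_kind == "brand_generic"),
      n_molecule_change = sum(switch_kind == "molecule"),
      n_analysis = sum(switch_kind == "none")
    ), by = group])
  list(cohort = ev[switch_kind == "none"][], switchers = counts)
}

#' Osteoporotic fracture history
#'
#' `TRUE` for patients with any hospitalization whose diagnosis matches the
#' configured fracture code list within the lookback window before index.
#'
#' @param index_events Index events with `patient_id`, `index_date`.
#' @param hospitalizations Hospitalization table.
#' @param config A [cohort_config()].
#' @return Logical vector aligned with `index_events` rows.
#' @export
fracture_history <- function(index_events, hospitalizations,
                             config = cohort_config()) {
  ev <- as.data.table(index_events)
  hosp <- as.data.table(hospitalizations)
  if (nrow(hosp) == 0L) return(rep(FALSE, nrow(ev)))
  hosp[, admission_date := parse_claim_dates(admission_date, "hospitalizations")]
  hit <- hosp[icd_match(icd10, config$fracture_icd)]
  hit <- hit[ev[, .(patient_id, index_date)], on = "patient_id", nomatch = NULL]
  hit <- hit[admission_date < index_date &
               admission_date >= index_date - config$lookback_days]
  ev$patient_id %in% unique(hit$patient_id)
}

#' Build the analysis cohort from claims tables
#'
#' Chains new-user identification, exclusion rules, switcher removal and
#' derivation of the fracture-history covariate, returning the analysis
#' cohort with one row per patient alongside the full attrition record and
#' switcher counts.
#'
#' @param tables A `claims_bundle` from [simulate_claims()] or a list with
#'   elements `dispensing`, `patients`, `hospitalizations`.
#' @param config A [cohort_config()].
#' @return A list of class `adherence_cohort`: `cohort`, `attrition`,
#'   `switchers`, `config`.
#' @export
build_cohort <- function(tables, config = cohort_config()) {
  nu <- identify_new_users(tables$dispensing, tables$patients, config)
  ex <- apply_exclusions(nu$index_events, tables$dispensing,
                         tables$hospitalizations, config, nu$attrition)
  sw <- detect_switchers(ex$index_events, tables$dispensing,
                         config$followup_days)
  cohort <- sw$cohort
  attrition <- append_attrition(ex$attrition, "no switch within follow-up",
                                nrow(cohort))
  cohort[, fracture_history := fracture_history(cohort,
                                                tables$hospitalizations,
                                                config)]
  cohort[, year := as.integer(format(index_date, "%Y"))]
  structure(list(cohort = cohort[], attrition = attrition,
                 switchers = sw$switchers, config = config),
            class = "adherence_cohort")
}

#' @export
print.adherence_cohort <- function(x, ...) {
  cat("Analysis cohort:", nrow(x$cohort), "patients (",
      sum(x$cohort$group == "brand"), "brand /",
      sum(x$cohort$group == "generic"), "generic )\n")
  print(x$attrition)
  invisible(x)
}

#' Read a claims bundle back from delimited files
#'
#' Counterpart of [write_claims()]: reads the four CSV tables from `dir`.
#'
#' @param dir Directory containing `patients.csv`, `dispensing.csv`,
#'   `hospitalizations.csv`, `deaths.csv`.
#' @return A list with the four tables as `data.table`s.
#' @export
read_claims <- function(dir) {
  need <- c("patients.csv", "dispensing.csv", "hospitalizations.csv",
            "deaths.csv")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(file.path(dir, missing),
                                          collapse = ", "), call. = FALSE)
  }
  out <- lapply(paths, function(p) as.data.table(utils::read.csv(p)))
  names(out) <- c("patients", "dispensing", "hospitalizations", "deaths")
  for (dc in c("index_date", "observation_start")) {
    if (dc %in% names(out$patients)) {
      out$patients[[dc]] <- as.Date(out$patients[[dc]])
    }
  }
  out$dispensing$date <- as.Date(out$dispensing$date)
  if (nrow(out$hospitalizations)) {
    out$hospitalizations$admission_date <-
      as.Date(out$hospitalizations$admission_date)
    out$hospitalizations$discharge_date <-
      as.Date(out$hospitalizations$discharge_date)
  }
  if (nrow(out$deaths)) out$deaths$death_date <- as.Date(out$deaths$death_date)
  out
}
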