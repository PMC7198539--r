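#' @import data.table
NULL

# Table-1-like marginals for the emulated covariates
COVARIATE_MARGINALS <- list(
  age_mean = 70.4, age_sd = 10.5, age_min = 50, age_max = 100,
  p_female = 0.892, p_ald = 0.420, p_cmu = 0.025, p_polypharmacy = 0.703,
  p_fracture = 0.054,
  charlson_levels = c("0", "1-2", ">=3"),
  charlson_probs = c(0.661, 0.335, 0.004),
  years = 2009:2015,
  year_probs = c(1254, 1095, 1111, 880, 767, 788, 717) / 6612,
  freq_levels = c("daily", "weekly", "monthly"),
  freq_probs = c(0.020, 0.583, 0.397),
  spec_levels = c("general", "specialist", "hospital", "unknown"),
  spec_probs = c(0.659, 0.180, 0.156, 0.005),
  molecules = c("alendronic", "risedronic", "ibandronic", "etidronic"),
  mol_probs_brand = c(0.088, 0.535, 0.369, 0.008),
  mol_probs_generic = c(0.473, 0.522, 0.000, 0.005)
)

# Default ICD-10 prefixes for osteoporotic fracture history
#' Default ICD-10 code lists
#'
#' `default_fracture_codes()` returns the hip/vertebral/humerus/forearm/
#' tibia/fibula fracture prefixes used for the 24-month fracture-history
#' covariate; `default_exclusion_codes()` the secondary-osteoporosis and
#' gastro-intestinal diagnosis prefixes whose pre-index hospitalization
#' excludes a patient. Both lists are configurable inputs, not hard-coded
#' nosology: pass your own lists to [cohort_config()] to override.
#'
#' @return Character vector of dot-stripped ICD-10 prefixes.
#' @export
default_fracture_codes <- function() {
  c("S720", "S7200", "S721", "S7210", "S722", "S7220",
    "S220", "S2200", "S221", "S2210", "S320", "S3200", "S327", "S3270",
    "S422", "S4220", "S525", "S5250", "S526", "S5260",
    "S821", "S8210", "S824", "S8240")
}

#' @rdname default_fracture_codes
#' @export
default_exclusion_codes <- function() {
  c("C795", "E24", "C900", "M88",
    "K20", "K21", "K221", "K222", "K223", "K226", "K228",
    "K25", "K26", "K27", "K28", "K290", "K297", "K298", "K299",
    "K30", "K920", "K921", "K922",
    "E05", "E06", "E210", "E211", "E212", "E213")
}

# calibrate the assignment-model intercept so mean(plogis(c + lp)) = target
calibrate_intercept <- function(lp, target) {
  f <- function(c0) mean(stats::plogis(c0 + lp)) - target
  stats::uniroot(f, c(-25, 25), tol = 1e-10)$root
}

#' Generate the patient table of a synthetic claims cohort
#'
#' Draws baseline covariates from fixed marginals emulating a French
#' osteoporosis new-user population, assigns the brand/generic group by a
#' logistic model on those covariates (intercept calibrated to the target
#' marginal share, so confounding of treatment assignment is real), and
#' draws each patient's latent course: stop day of treatment (geometric on
#' follow-up days), adherence class, and death day.
#'
#' @param params A [simulation_params()] object.
#' @return A `data.table` with one row per patient: identifiers, index date,
#'   covariates, and latent columns (`group`, `stop_day`, `death_day`,
#'   `adherent_class`) consumed by the other generators and exported as
#'   ground truth.
#' @export
generate_patients <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  m <- COVARIATE_MARGINALS
  n <- params$n_patients

  age <- pmin(pmax(stats::rnorm(n, m$age_mean, m$age_sd), m$age_min), m$age_max)
  age <- round(age, 1)
  female <- stats::rbinom(n, 1, m$p_female) == 1
  ald <- stats::rbinom(n, 1, m$p_ald) == 1
  cmu <- stats::rbinom(n, 1, m$p_cmu) == 1
  polypharmacy <- stats::rbinom(n, 1, m$p_polypharmacy) == 1
  fracture <- stats::rbinom(n, 1, m$p_fracture) == 1
  charlson <- sample(m$charlson_levels, n, TRUE, m$charlson_probs)
  year <- sample(m$years, n, TRUE, m$year_probs)
  freq <- sample(m$freq_levels, n, TRUE, m$freq_probs)
  specialty <- sample(m$spec_levels, n, TRUE, m$spec_probs)

  eff <- params$covariate_effects
  e <- function(name) if (name %in% names(eff)) eff[[name]] else 0
  lp <- e("age") * (age - 70) +
    e("female") * female + e("cmu") * cmu +
    e("polypharmacy") * polypharmacy +
    e("charlson_1_2") * (charlson == "1-2") +
    e("charlson_3plus") * (charlson == ">=3") +
    e("fracture") * fracture +
    e("year") * (year - 2012) +
    e("freq_daily") * (freq == "daily") +
    e("freq_monthly") * (freq == "monthly") +
    e("spec_specialist") * (specialty == "specialist") +
    e("spec_hospital") * (specialty == "hospital")
  c0 <- calibrate_intercept(lp, params$brand_share)
  brand <- stats::runif(n) < stats::plogis(c0 + lp)
  group <- ifelse(brand, "brand", "generic")

  mol <- character(n)
  nb <- sum(brand)
  if (nb > 0) {
    mol[brand] <- sample(m$molecules, nb, TRUE, m$mol_probs_brand)
  }
  if (nb < n) {
    mol[!brand] <- sample(m$molecules, n - nb, TRUE, m$mol_probs_generic)
  }

  # latent stop day: geometric per day of follow-up, so the day-scale
  # discontinuation hazard ratio equals the parameter ratio exactly; the
  # patient collects every refill scheduled on or before this day
  h <- ifelse(brand, params$discontinuation_hazard_brand,
              params$discontinuation_hazard_generic)
  stop_day <- rep(Inf, n)
  pos <- h > 0
  if (any(pos)) stop_day[pos] <- stats::rgeom(sum(pos), h[pos])

  p_good <- ifelse(brand, params$good_implementation_rr * params$p_good_generic,
                   params$p_good_generic)
  adherent_class <- ifelse(stats::runif(n) < p_good, "tight", "loose")
  if (!params$implementation_classes) adherent_class <- rep("jitter", n)

  dies <- stats::rbinom(n, 1, params$death_rate) == 1
  death_day <- rep(NA_integer_, n)
  death_day[dies] <- sample.int(params$followup_days, sum(dies), replace = TRUE)

  index_date <- as.Date(paste0(year, "-01-01")) +
    sample.int(365L, n, replace = TRUE) - 1L

  data.table(
    patient_id = sprintf("P%05d", seq_len(n)),
    index_date = index_date,
    observation_start = index_date - 1100L,
    age = age,
    sex = ifelse(female, "F", "M"),
    ald = ald, cmu = cmu, polypharmacy = polypharmacy,
    fracture_latent = fracture,
    charlson = charlson,
    year = year,
    frequency = freq,
    specialty = specialty,
    molecule = mol,
    group = group,
    stop_day = stop_day,
    death_day = death_day,
    adherent_class = adherent_class
  )
}

# per-event refill delay in days given adherence class and supply
refill_delays <- function(class, supply, params) {
  n <- length(class)
  d <- integer(n)
  tight <- class == "tight"
  loose <- class == "loose"
  jitter <- class == "jitter"
  if (any(tight)) d[tight] <- sample(seq.int(-3L, 2L), sum(tight), TRUE)
  if (any(loose)) {
    frac <- stats::runif(sum(loose), 0.25, 0.40)
    d[loose] <- as.integer(round(frac * supply[loose]))
  }
  if (any(jitter)) d[jitter] <- draw_dist(params$refill_delay, sum(jitter),
                                          "refill_delay")
  d
}

#' Generate the dispensing table
#'
#' Emits each patient's index dispensation at day 0 of their follow-up
#' clock, then refills at supply-duration-plus-delay intervals until the
#' latent stop day, death, or the end of follow-up. Package
#' size (1 or 3 months, i.e. 30 or 90 days of supply) is drawn per event.
#' Brand/generic flags and molecule are constant within patient unless
#' `switch_rate > 0`, in which case selected patients flip brand status or
#' change molecule from a random later dispensation onward (to exercise
#' switcher exclusion).
#'
#' @param params A [simulation_params()] object.
#' @param patients Output of [generate_patients()].
#' @return A `data.table` of dispensations: `patient_id`, `date`, `day`
#'   (offset from index), `drug_class`, `molecule`, `brand`,
#'   `package_months`, `supply_days`.
#' @export
generate_dispensing <- function(params, patients) {
  n <- nrow(patients)
  fu <- params$followup_days
  death <- ifelse(is.na(patients$death_day), Inf, patients$death_day)

  cur_day <- rep(0L, n)
  active <- cur_day <= patients$stop_day & cur_day < fu & cur_day < death
  rows <- vector("list", 0L)
  while (any(active)) {
    idx <- which(active)
    k <- length(idx)
    pkg3 <- stats::runif(k) < params$package_mix
    supply <- ifelse(pkg3, 90L, 30L)
    rows[[length(rows) + 1L]] <- data.table(
      patient_id = patients$patient_id[idx],
      day = cur_day[idx],
      package_months = ifelse(pkg3, 3L, 1L),
      supply_days = as.integer(supply)
    )
    delay <- refill_delays(patients$adherent_class[idx], supply, params)
    nxt <- cur_day[idx] + pmax(as.integer(supply) + delay, 1L)
    cur_day[idx] <- nxt
    active <- cur_day <= patients$stop_day & cur_day < fu & cur_day < death
  }
  disp <- rbindlist(rows)
  setkey(disp, patient_id, day)
  disp <- merge(disp,
                patients[, c("patient_id", "index_date", "molecule", "group")],
                by = "patient_id")
  disp[, `:=`(brand = group == "brand", drug_class = "bisphosphonate",
              date = index_date + day)]
  disp[, c("index_date", "group") := NULL]

  if (params$switch_rate > 0) {
    counts <- disp[, .N, by = patient_id]
    eligible <- counts[counts$N >= 2L, ]
    pick <- eligible$patient_id[stats::runif(nrow(eligible)) < params$switch_rate]
    if (length(pick)) {
      kind <- sample(c("brand_generic", "molecule"), length(pick), TRUE)
      at <- vapply(pick, function(p) {
        nn <- counts$N[counts$patient_id == p]
        sample(2:nn, 1L)
      }, integer(1))
      for (i in seq_along(pick)) {
        ri <- which(disp$patient_id == pick[i])
        tail_rows <- ri[at[i]:length(ri)]
        if (kind[i] == "brand_generic") {
          disp[tail_rows, brand := !disp$brand[tail_rows]]
        } else {
          other <- setdiff(COVARIATE_MARGINALS$molecules,
                           disp$molecule[tail_rows[1]])
          disp[tail_rows, molecule := sample(other, 1L)]
        }
      }
      attr(disp, "switch_kind") <- data.table(patient_id = pick, kind = kind)
    }
  }
  setcolorder(disp, c("patient_id", "date", "day", "drug_class", "molecule",
                      "brand", "package_months", "supply_days"))
  setkey(disp, patient_id, day)
  disp[]
}

#' Generate the hospitalization table
#'
#' In-window stays arrive as a Poisson process at `hosp_rate` per
#' patient-year of follow-up (follow-up truncated at death) with durations
#' from `hosp_duration`; they may overlap refill gaps, which is what the
#' gap-deduction and coverage-extension rules consume. Patients whose latent
#' fracture-history flag is set additionally receive one pre-index stay
#' carrying an osteoporotic-fracture diagnosis code, and (optionally) a
#' fraction of patients receive a pre-index stay with a diagnosis on the
#' exclusion list.
#'
#' @inheritParams generate_dispensing
#' @return A `data.table`: `patient_id`, `admission_date`, `discharge_date`,
#'   `admission_day`, `discharge_day` (offsets from index; half-open
#'   interval), `icd10`.
#' @export
generate_hospitalizations <- function(params, patients) {
  fu <- params$followup_days
  death <- ifelse(is.na(patients$death_day), fu, pmin(patients$death_day, fu))
  n_stay <- stats::rpois(nrow(patients), params$hosp_rate * death / 365)
  idx <- rep(seq_len(nrow(patients)), n_stay)
  out <- list()
  if (length(idx)) {
    admit <- floor(stats::runif(length(idx)) * death[idx])
    dur <- draw_dist(params$hosp_duration, length(idx), "hosp_duration")
    disch <- pmin(admit + dur, death[idx])
    out$inwindow <- data.table(
      patient_id = patients$patient_id[idx],
      admission_day = as.integer(admit),
      discharge_day = as.integer(disch),
      icd10 = "Z518"
    )
  }
  fr <- which(patients$fracture_latent)
  if (length(fr)) {
    admit <- -sample(30:700, length(fr), TRUE)
    out$fracture <- data.table(
      patient_id = patients$patient_id[fr],
      admission_day = as.integer(admit),
      discharge_day = as.integer(admit + sample(3:10, length(fr), TRUE)),
      icd10 = sample(c("S72.0", "S32.0", "S42.2", "S52.5", "S82.1"),
                     length(fr), TRUE)
    )
  }
  if (params$exclusion_hosp_rate > 0) {
    ex <- which(stats::runif(nrow(patients)) < params$exclusion_hosp_rate)
    if (length(ex)) {
      admit <- -sample(30:700, length(ex), TRUE)
      out$excl <- data.table(
        patient_id = patients$patient_id[ex],
        admission_day = as.integer(admit),
        discharge_day = as.integer(admit + sample(3:15, length(ex), TRUE)),
        icd10 = sample(c("C90.0", "M88.9", "K25.0", "E24.0"), length(ex), TRUE)
      )
    }
  }
  hosp <- rbindlist(out)
  if (nrow(hosp) == 0L) {
    hosp <- data.table(patient_id = character(0), admission_day = integer(0),
                       discharge_day = integer(0), icd10 = character(0))
  }
  hosp <- merge(hosp, patients[, c("patient_id", "index_date")],
                by = "patient_id")
  hosp[, `:=`(admission_date = index_date + admission_day,
              discharge_date = index_date + discharge_day)]
  hosp[, index_date := NULL]
  setcolorder(hosp, c("patient_id", "admission_date", "discharge_date",
                      "admission_day", "discharge_day", "icd10"))
  setkey(hosp, patient_id, admission_day)
  hosp[]
}

#' Simulate a complete synthetic claims bundle
#'
#' Runs the full data-generating process under one seed: patients,
#' dispensing events, hospitalizations, deaths, pre-index corticosteroid
#' reimbursements (if `cortico_rate > 0`), and the ground-truth table used
#' by parameter-recovery tests. Identical parameters (including the seed)
#' give byte-identical tables.
#'
#' @param params A [simulation_params()] object.
#' @return A list of class `claims_bundle`: `patients`, `dispensing`,
#'   `hospitalizations`, `deaths`, `ground_truth`, `params`. The
#'   ground-truth table records each patient's latent assignment; its
#'   attributes `true_brand_share`, `true_hr` (ratio of per-cycle
#'   discontinuation hazards, brand/generic) and `true_rr` give the marginal
#'   truths of the design.
#' @examples
#' sim <- simulate_claims(simulation_params(n_patients = 200, seed = 42))
#' nrow(sim$patients)
#' @export
simulate_claims <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  patients <- generate_patients(params)
  dispensing <- generate_dispensing(params, patients)
  hospitalizations <- generate_hospitalizations(params, patients)

  deaths <- patients[!is.na(patients$death_day),
                     c("patient_id", "index_date", "death_day")]
  deaths <- data.table(patient_id = deaths$patient_id,
                       death_date = deaths$index_date + deaths$death_day,
                       death_day = deaths$death_day)

  if (params$cortico_rate > 0) {
    ci <- which(stats::runif(nrow(patients)) < params$cortico_rate)
    if (length(ci)) {
      cor <- data.table(
        patient_id = rep(patients$patient_id[ci], each = 3L),
        day = rep(c(-150L, -90L, -30L), length(ci)),
        package_months = NA_integer_, supply_days = NA_integer_,
        molecule = "prednisone", brand = NA,
        drug_class = "corticosteroid"
      )
      cor <- merge(cor, patients[, c("patient_id", "index_date")],
                   by = "patient_id")
      cor[, date := index_date + day]
      cor[, index_date := NULL]
      dispensing <- rbindlist(list(dispensing, cor), use.names = TRUE)
      setkey(dispensing, patient_id, day)
    }
  }

  truth <- patients[, c("patient_id", "group", "stop_day", "death_day",
                        "adherent_class")]
  sw <- attr(dispensing, "switch_kind")
  truth[, switch_kind := "none"]
  if (!is.null(sw)) {
    truth[sw, on = "patient_id", switch_kind := sw$kind[match(patient_id, sw$patient_id)]]
  }
  setattr(truth, "true_brand_share", params$brand_share)
  setattr(truth, "true_hr", params$discontinuation_hazard_brand /
            params$discontinuation_hazard_generic)
  setattr(truth, "true_rr",
          if (params$implementation_classes) params$good_implementation_rr
          else NA_real_)
  setattr(truth, "seed", params$seed)

  structure(list(patients = patients, dispensing = dispensing,
                 hospitalizations = hospitalizations, deaths = deaths,
                 ground_truth = truth, params = params),
            class = "claims_bundle")
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("Synthetic claims bundle:", nrow(x$patients), "patients,",
      nrow(x$dispensing), "dispensations,",
      nrow(x$hospitalizations), "hospital stays,",
      nrow(x$deaths), "deaths (seed", x$params$seed, ")\n")
  invisible(x)
}

#' Write a claims bundle to delimited files
#'
#' Writes `patients.csv`, `dispensing.csv`, `hospitalizations.csv`,
#' `deaths.csv` (all dates ISO-8601) and `ground_truth.json` into `dir`.
#'
#' @param bundle A `claims_bundle` from [simulate_claims()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_claims <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  drop_latent <- c("stop_day", "death_day", "adherent_class",
                   "fracture_latent", "group")
  pat <- as.data.frame(bundle$patients)[
    , setdiff(names(bundle$patients), drop_latent)]
  paths <- file.path(dir, c("patients.csv", "dispensing.csv",
                            "hospitalizations.csv", "deaths.csv",
                            "ground_truth.json"))
  utils::write.csv(pat, paths[1], row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$dispensing), paths[2], row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$hospitalizations), paths[3],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$deaths), paths[4], row.names = FALSE)
  export_ground_truth(bundle, paths[5])
  invisible(paths)
}

#' Export the ground-truth table
#'
#' Machine-readable latent truth for recovery tests: per-patient group,
#' latent stop day, death day, adherence class and switch
#' kind, plus the design-level truths (marginal brand share, true hazard
#' ratio, true implementation risk ratio, seed).
#'
#' @param bundle A `claims_bundle`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
export_ground_truth <- function(bundle, path) {
  stopifnot(inherits(bundle, "claims_bundle"))
  tr <- as.data.frame(bundle$ground_truth)
  tr$stop_day[is.infinite(tr$stop_day)] <- NA  # never stops within follow-up
  obj <- list(
    true_brand_share = attr(tr, "true_brand_share"),
    true_hr = attr(tr, "true_hr"),
    true_rr = attr(tr, "true_rr"),
    seed = attr(bundle$ground_truth, "seed"),
    patients = tr
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
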