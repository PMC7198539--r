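#' Days of supply of a drug package
#'
#' Packages cover 1 or 3 months of treatment at the defined daily dose;
#' the fixed convention is 30 and 90 days so every downstream computation
#' stays on an exact integer day grid.
#'
#' @param package_months Integer vector of package sizes (1 or 3).
#' @return Integer days of supply (30 or 90).
#' @export
infer_supply_duration <- function(package_months) {
  if (any(!package_months %in% c(1L, 3L))) {
    stop("unsupported package size: ",
         paste(unique(setdiff(package_months, c(1, 3))), collapse = ", "),
         " (must be 1 or 3 months)", call. = FALSE)
  }
  ifelse(package_months == 3L, 90L, 30L)
}

#' Deduct hospitalized days from a refill gap
#'
#' When the interval between two dispensations (half-open, in days from
#' index) contains hospital days, those days are deducted before the gap is
#' compared with the refill allowance: in-hospital patients are supplied by
#' the hospital, so the gap does not evidence discontinuation. Overlapping
#' stays are merged before deduction.
#'
#' @param gap_start,gap_end Half-open gap interval `[gap_start, gap_end)`.
#' @param hosp Data frame of stays with `admission_day`, `discharge_day`
#'   (half-open), or `NULL`.
#' @return Net gap length in days (never negative).
#' @examples
#' adjust_gap_for_hospitalization(0, 70,
#'   data.frame(admission_day = 20, discharge_day = 35))
#' @export
adjust_gap_for_hospitalization <- function(gap_start, gap_end, hosp = NULL) {
  len <- max(gap_end - gap_start, 0L)
  if (is.null(hosp) || NROW(hosp) == 0L) return(len)
  m <- merge_intervals(hosp$admission_day, hosp$discharge_day)
  len - overlap_days(m$start, m$end, gap_start, gap_end)
}

#' Detect treatment discontinuation in one episode
#'
#' Scans consecutive dispensations: the patient discontinues at the first
#' event whose successor arrives more than `gap_multiplier` times that
#' event's days of supply after the anchor (the dispensing date by default,
#' or supply exhaustion with `anchor = "exhaustion"`), after deducting
#' hospitalized days from the gap; or at the last event when the allowance
#' expires inside follow-up with no further dispensation. The time to
#' discontinuation is the discontinuing event's day plus its days of
#' supply. Death before that point censors the patient at the death day;
#' otherwise the patient is persistent, censored at the end of follow-up.
#'
#' @param events Data frame with `day` (integer offsets from index, first
#'   row at 0) and `supply_days`, sorted by day.
#' @param hosp Hospital stays (`admission_day`, `discharge_day`) or `NULL`.
#' @param death_day Day of death or `NA`.
#' @param followup_days Follow-up length (administrative censoring).
#' @param gap_multiplier Allowance multiplier on the previous supply.
#' @param anchor `"dispensation"` (allowance runs from the dispensing date)
#'   or `"exhaustion"` (from the end of the supplied period).
#' @return A list: `status` (`"persistent"`, `"discontinued"`, `"died"`),
#'   `time_to_discontinuation` (days, `NA` unless discontinued),
#'   `censor_day`.
#' @export
detect_discontinuation <- function(events, hosp = NULL, death_day = NA,
                                   followup_days = 365L, gap_multiplier = 2,
                                   anchor = c("dispensation", "exhaustion")) {
  anchor <- match.arg(anchor)
  if (NROW(events) == 0L) stop("episode has no dispensing events", call. = FALSE)
  d <- as.integer(events$day)
  s <- as.integer(events$supply_days)
  if (is.unsorted(d)) {
    o <- order(d); d <- d[o]; s <- s[o]
  }
  k <- length(d)
  disc_time <- NA_integer_
  for (i in seq_len(k)) {
    allowance <- gap_multiplier * s[i] + if (anchor == "exhaustion") s[i] else 0L
    gap_end <- if (i < k) d[i + 1L] else followup_days
    net <- adjust_gap_for_hospitalization(d[i], gap_end, hosp)
    if (net > allowance) {
      disc_time <- d[i] + s[i]
      break
    }
  }
  dd <- if (is.na(death_day)) Inf else death_day
  if (!is.na(disc_time) && dd >= disc_time) {
    list(status = "discontinued", time_to_discontinuation = disc_time,
         censor_day = disc_time)
  } else if (dd <= followup_days) {
    list(status = "died", time_to_discontinuation = NA_integer_,
         censor_day = as.integer(dd))
  } else {
    list(status = "persistent", time_to_discontinuation = NA_integer_,
         censor_day = as.integer(followup_days))
  }
}

#' CMA7: continuous multiple-interval measure of medication availability
#'
#' Proportion of window days covered by supply, assuming full adherence
#' until each supply runs out, carrying any unconsumed supply at a new
#' dispensation over to the next interval (uncapped), and treating
#' hospitalized days as covered while freezing supply consumption (the
#' hospital supplies the drug, so remaining home supply extends
#' accordingly). Computed on the half-open integer day grid
#' `[0, window_days)` of the persistence window.
#'
#' @param events Data frame with `day` and `supply_days`, first event at
#'   day 0.
#' @param hosp Hospital stays (`admission_day`, `discharge_day`) or `NULL`.
#' @param window_days Window length in days (> 0): time to discontinuation,
#'   death day, or the follow-up end, whichever comes first.
#' @param threshold Good-implementation cutoff (closed at the top:
#'   `cma7 >= threshold` is good).
#' @return A list: `covered_days`, `window_days`, `cma7`, `good`.
#' @examples
#' compute_cma7(data.frame(day = c(0, 40), supply_days = c(30, 30)),
#'              window_days = 70)
#' @export
compute_cma7 <- function(events, hosp = NULL, window_days,
                         threshold = 0.90) {
  if (window_days <= 0) stop("window length must be positive", call. = FALSE)
  d <- as.integer(events$day)
  s <- as.integer(events$supply_days)
  o <- order(d); d <- d[o]; s <- s[o]
  keep <- d < window_days
  d <- d[keep]; s <- s[keep]
  if (length(d) == 0L) stop("no dispensing event inside the window", call. = FALSE)

  hm <- if (is.null(hosp) || NROW(hosp) == 0L) {
    data.frame(start = integer(0), end = integer(0))
  } else {
    merge_intervals(pmax(hosp$admission_day, 0L),
                    pmin(hosp$discharge_day, window_days))
  }

  seg_start <- d
  seg_end <- c(d[-1L], window_days)
  seg_end <- pmin(seg_end, window_days)
  H <- vapply(seq_along(seg_start), function(i) {
    overlap_days(hm$start, hm$end, seg_start[i], seg_end[i])
  }, numeric(1))
  len <- pmax(seg_end - seg_start, 0L)
  N <- len - H

  # supply ledger: stock after each segment follows a Lindley recursion,
  # so consumption totals drop out of cumulative sums
  cdelta <- cumsum(s - N)
  stock_last <- cdelta[length(cdelta)] - min(0, min(cummin(cdelta)))
  consumed <- sum(s) - stock_last
  covered <- sum(H) + consumed
  covered <- min(covered, window_days)
  cma <- covered / window_days
  list(covered_days = as.integer(covered), window_days = as.integer(window_days),
       cma7 = cma, good = cma >= threshold)
}

# clip hospital stays to the follow-up window and merge per patient
prep_hosp_days <- function(hospitalizations, followup_days) {
  hosp <- as.data.table(hospitalizations)
  if (nrow(hosp) == 0L ||
      !all(c("admission_day", "discharge_day") %in% names(hosp))) {
    return(data.table(patient_id = character(0), start = integer(0),
                      end = integer(0)))
  }
  hosp <- hosp[discharge_day > 0 & admission_day < followup_days]
  if (nrow(hosp) == 0L) {
    return(data.table(patient_id = character(0), start = integer(0),
                      end = integer(0)))
  }
  hosp[, `:=`(start = pmax(admission_day, 0L),
              end = pmin(discharge_day, followup_days))]
  hosp[, {
    m <- merge_intervals(start, end)
    list(start = m$start, end = m$end)
  }, by = patient_id]
}

#' Build resolved treatment episodes for an analysis cohort
#'
#' Assembles each patient's supply events on the day grid of their
#' follow-up clock, applies the refill-gap discontinuation rule with
#' hospital-day deduction, resolves the persistence status against death
#' and administrative censoring, and computes CMA7 over the persistence
#' window for patients under treatment at least `eligibility_days` days.
#'
#' @param cohort An `adherence_cohort` from [build_cohort()], or its
#'   `cohort` table.
#' @param dispensing Dispensing table.
#' @param hospitalizations Hospitalization table (with `admission_day`,
#'   `discharge_day` offsets, or dates plus patient index dates).
#' @param deaths Death table with `patient_id` and `death_day` or
#'   `death_date`.
#' @param followup_days Follow-up length.
#' @param gap_multiplier Refill-gap allowance multiplier.
#' @param anchor Gap anchor, see [detect_discontinuation()].
#' @param cma_threshold Good-implementation cutoff.
#' @param eligibility_days Minimum persistence for the implementation
#'   analysis (183 days = 6 months).
#' @return A `data.table` of class `treatment_episodes`, one row per
#'   patient: `group`, `n_events`, `status`, `time_to_discontinuation`,
#'   `censor_day`, `end_day`, `eligible`, `covered_days`, `window_days`,
#'   `cma7`, `good`.
#' @export
build_episodes <- function(cohort, dispensing, hospitalizations = NULL,
                           deaths = NULL, followup_days = 365L,
                           gap_multiplier = 2,
                           anchor = c("dispensation", "exhaustion"),
                           cma_threshold = 0.90,
                           eligibility_days = 183L) {
  anchor <- match.arg(anchor)
  if (inherits(cohort, "adherence_cohort")) cohort <- cohort$cohort
  co <- as.data.table(cohort)[, .(patient_id, index_date, group)]

  disp <- as.data.table(dispensing)[drug_class == "bisphosphonate"]
  disp[, date := parse_claim_dates(date, "dispensing")]
  ev <- disp[co, on = "patient_id", nomatch = NULL]
  ev[, day := as.integer(date - index_date)]
  ev <- ev[day >= 0L & day < followup_days]
  if ("supply_days" %in% names(ev) && !anyNA(ev$supply_days)) {
    ev[, supply := as.integer(supply_days)]
  } else {
    ev[, supply := infer_supply_duration(package_months)]
  }
  setorder(ev, patient_id, day)

  hosp <- as.data.table(hospitalizations %||%
                          data.frame(patient_id = character(0)))
  if (nrow(hosp) && !"admission_day" %in% names(hosp)) {
    hosp <- hosp[co, on = "patient_id", nomatch = NULL]
    hosp[, `:=`(admission_day = as.integer(parse_claim_dates(admission_date,
                                                             "hospitalizations") - index_date),
                discharge_day = as.integer(parse_claim_dates(discharge_date,
                                                             "hospitalizations") - index_date))]
  }
  hdays <- prep_hosp_days(hosp, followup_days)

  dth <- as.data.table(deaths %||% data.frame(patient_id = character(0)))
  if (nrow(dth) && !"death_day" %in% names(dth)) {
    dth <- dth[co, on = "patient_id", nomatch = NULL]
    dth[, death_day := as.integer(parse_claim_dates(death_date, "deaths") -
                                    index_date)]
  }

  # gap scan: raw gap per event, hospital deduction only where it matters
  ev[, `:=`(nxt = shift(day, -1L), idx = seq_len(.N)), by = patient_id]
  ev[, gap_end := fifelse(is.na(nxt), as.integer(followup_days), nxt)]
  ev[, allowance := gap_multiplier * supply +
       (anchor == "exhaustion") * supply]
  cand <- ev[(gap_end - day) > allowance]
  if (nrow(cand) && nrow(hdays)) {
    ov <- hdays[cand[, .(patient_id, day, gap_end, rid = .I)],
                on = .(patient_id, end > day, start < gap_end),
                nomatch = NULL,
                .(rid = i.rid,
                  days = pmin(x.end, i.gap_end) - pmax(x.start, i.day))]
    if (nrow(ov)) {
      ded <- ov[, .(hdays = sum(days)), by = rid]
      cand[ded$rid, net_extra := ded$hdays]
    }
  }
  if (nrow(cand)) {
    if (!"net_extra" %in% names(cand)) cand[, net_extra := 0L]
    cand[is.na(net_extra), net_extra := 0L]
    cand <- cand[(gap_end - day - net_extra) > allowance]
  }
  disc <- if (nrow(cand)) {
    cand[, .(disc_time = day[which.min(idx)] + supply[which.min(idx)]),
         by = patient_id]
  } else {
    data.table(patient_id = character(0), disc_time = integer(0))
  }

  epi <- ev[, .(n_events = .N, last_day = max(day),
                last_supply = supply[.N]), by = .(patient_id, group)]
  epi <- merge(epi, disc, by = "patient_id", all.x = TRUE)
  if (nrow(dth)) {
    epi <- merge(epi, dth[, .(patient_id, death_day)], by = "patient_id",
                 all.x = TRUE)
  } else {
    epi[, death_day := NA_integer_]
  }
  epi[, status := fifelse(
    !is.na(disc_time) & (is.na(death_day) | death_day >= disc_time),
    "discontinued",
    fifelse(!is.na(death_day) & death_day <= followup_days, "died",
            "persistent"))]
  epi[, time_to_discontinuation := fifelse(status == "discontinued",
                                           disc_time, NA_integer_)]
  epi[, censor_day := fifelse(status == "discontinued", disc_time,
                              fifelse(status == "died", death_day,
                                      as.integer(followup_days)))]
  epi[, end_day := censor_day]
  epi[, eligible := end_day >= eligibility_days]

  cma <- cma7_vectorized(ev[patient_id %in% epi$patient_id[epi$eligible]],
                         hdays, epi[eligible == TRUE, .(patient_id, end_day)],
                         cma_threshold)
  epi <- merge(epi, cma, by = "patient_id", all.x = TRUE)
  epi[, c("disc_time") := NULL]
  setattr(epi, "class", c("treatment_episodes", class(epi)))
  setattr(epi, "cma_threshold", cma_threshold)
  setattr(epi, "eligibility_days", eligibility_days)
  setattr(epi, "followup_days", as.integer(followup_days))
  epi[]
}

# vectorized CMA7 ledger across patients (same semantics as compute_cma7)
cma7_vectorized <- function(ev, hdays, windows, threshold) {
  if (nrow(windows) == 0L) {
    return(data.table(patient_id = character(0), covered_days = integer(0),
                      window_days = integer(0), cma7 = numeric(0),
                      good = logical(0)))
  }
  seg <- ev[windows, on = "patient_id", nomatch = NULL]
  seg <- seg[day < end_day]
  setorder(seg, patient_id, day)
  seg[, seg_end := pmin(fifelse(is.na(shift(day, -1L)), end_day,
                                shift(day, -1L)), end_day),
      by = patient_id]
  seg[, rid := .I]
  seg[, H := 0]
  if (nrow(hdays)) {
    ov <- hdays[seg[, .(patient_id, day, seg_end, rid)],
                on = .(patient_id, end > day, start < seg_end),
                nomatch = NULL,
                .(rid = i.rid,
                  days = pmin(x.end, i.seg_end) - pmax(x.start, i.day))]
    if (nrow(ov)) {
      hsum <- ov[, .(hd = sum(days)), by = rid]
      seg[hsum$rid, H := hsum$hd]
    }
  }
  seg[, N := (seg_end - day) - H]
  seg[, cdelta := cumsum(supply - N), by = patient_id]
  res <- seg[, {
    stock_last <- cdelta[.N] - min(0, min(cummin(cdelta)))
    covered <- min(sum(H) + sum(supply) - stock_last, end_day[1])
    list(covered_days = as.integer(covered),
         window_days = as.integer(end_day[1]))
  }, by = patient_id]
  res[, cma7 := covered_days / window_days]
  res[, good := cma7 >= threshold]
  res[]
}

#' Persistence summary by treatment group
#'
#' Per group: patients persistent at given horizons (still on treatment,
#' i.e. neither discontinued nor censored before the horizon), the half-up
#' one-decimal percentages, status counts, and the median \[Q1; Q3\] of the
#' time-to-discontinuation variable with persistent and censored patients
#' valued at the follow-up end (so the upper quartile can sit at 365, as in
#' administrative-censoring conventions).
#'
#' @param episodes A `treatment_episodes` table.
#' @param horizons Days at which persistence is evaluated.
#' @return A data.frame, one row per group.
#' @export
persistence_summary <- function(episodes, horizons = c(183L, 365L)) {
  ep <- as.data.table(episodes)
  fu <- attr(episodes, "followup_days") %||% 365L
  out <- ep[, {
    tv <- fifelse(status == "discontinued",
                  as.numeric(time_to_discontinuation), as.numeric(fu))
    q <- stats::quantile(tv, c(0.25, 0.5, 0.75), names = FALSE)
    row <- list(n = .N,
                n_discontinued = sum(status == "discontinued"),
                n_died = sum(status == "died"),
                median_time = q[2], q1_time = q[1], q3_time = q[3])
    for (h in horizons) {
      np <- sum(end_day >= h)
      row[[paste0("n_persistent_", h, "d")]] <- np
      row[[paste0("pct_persistent_", h, "d")]] <- pct1(np, .N)
    }
    row
  }, by = group]
  out <- as.data.frame(out)
  if (nrow(out) == 0L || any(out$n == 0L)) {
    attr(out, "empty_groups") <- TRUE
  }
  out
}

#' Classify implementation at the CMA7 threshold
#'
#' Two-class partition of eligible patients, closed at the top: `cma7 >=
#' threshold` is good implementation.
#'
#' @param episodes A `treatment_episodes` table (or any table with `group`,
#'   `eligible`, `cma7`).
#' @param threshold Cutoff, default 0.90.
#' @return A data.frame per group: eligible n, good/poor counts, half-up
#'   percentages, and mean/SD of CMA7.
#' @export
classify_implementation <- function(episodes, threshold = 0.90) {
  ep <- as.data.table(episodes)[eligible == TRUE & !is.na(cma7)]
  out <- ep[, {
    g <- sum(cma7 >= threshold)
    list(n_eligible = .N, n_good = g, n_poor = .N - g,
         pct_good = pct1(g, .N), pct_poor = pct1(.N - g, .N),
         mean_cma7 = mean(cma7), sd_cma7 = stats::sd(cma7))
  }, by = group]
  as.data.frame(out)
}

#' @export
print.treatment_episodes <- function(x, ...) {
  cat("Treatment episodes:", nrow(x), "patients\n")
  print(table(x$group, x$status))
  invisible(x)
}
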