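test_that("package size maps to fixed days of supply", {
  expect_identical(infer_supply_duration(c(1L, 3L)), c(30L, 90L))
  expect_error(infer_supply_duration(2L), "unsupported package size")
})

test_that("refill-gap rule flags discontinuation at the stated times", {
  # single 30-day dispensation, no refill: allowance expires, time = 30
  one <- detect_discontinuation(data.frame(day = 0, supply_days = 30))
  expect_identical(one$status, "discontinued")
  expect_identical(one$time_to_discontinuation, 30L)

  # refill at day 50 within the 60-day allowance, then nothing: time = 80
  two <- detect_discontinuation(data.frame(day = c(0, 50),
                                           supply_days = c(30, 30)))
  expect_identical(two$status, "discontinued")
  expect_identical(two$time_to_discontinuation, 80L)

  # steady refills through day 360: persistent at 12 months
  steady <- detect_discontinuation(data.frame(day = seq(0, 360, 30),
                                              supply_days = 30))
  expect_identical(steady$status, "persistent")
  expect_identical(steady$censor_day, 365L)

  # a late refill beyond twice the previous supply triggers the rule
  late <- detect_discontinuation(data.frame(day = c(0, 61, 91),
                                            supply_days = 30))
  expect_identical(late$status, "discontinued")
  expect_identical(late$time_to_discontinuation, 30L)
})

test_that("hospital days are deducted from refill gaps", {
  expect_equal(adjust_gap_for_hospitalization(0, 70, NULL), 70)
  hosp <- data.frame(admission_day = 20, discharge_day = 35)
  expect_equal(adjust_gap_for_hospitalization(0, 70, hosp), 55)
  full <- data.frame(admission_day = -5, discharge_day = 80)
  expect_equal(adjust_gap_for_hospitalization(0, 70, full), 0)
  # overlapping stays are merged, not double-deducted
  twice <- data.frame(admission_day = c(20, 25), discharge_day = c(35, 40))
  expect_equal(adjust_gap_for_hospitalization(0, 70, twice), 50)

  # 70-day gap with 15 hospital days stays within the 60-day allowance
  ep <- detect_discontinuation(data.frame(day = c(0, 70), supply_days = 30),
                               hosp = hosp)
  expect_identical(ep$time_to_discontinuation, 100L)  # not 30: first gap ok
  no_hosp <- detect_discontinuation(data.frame(day = c(0, 70),
                                               supply_days = 30))
  expect_identical(no_hosp$time_to_discontinuation, 30L)
})

test_that("death censors an episode only before the discontinuation point", {
  ev <- data.frame(day = 0, supply_days = 30)
  died <- detect_discontinuation(ev, death_day = 20)
  expect_identical(died$status, "died")
  expect_identical(died$censor_day, 20L)
  after <- detect_discontinuation(ev, death_day = 200)
  expect_identical(after$status, "discontinued")
  expect_error(detect_discontinuation(data.frame(day = integer(0),
                                                 supply_days = integer(0))),
               "no dispensing events")
})

test_that("CMA7 reproduces its worked examples", {
  expect_equal(compute_cma7(data.frame(day = 0, supply_days = 90),
                            window_days = 90)$cma7, 1.0)
  ex2 <- compute_cma7(data.frame(day = c(0, 40), supply_days = c(30, 30)),
                      window_days = 70)
  expect_identical(ex2$covered_days, 60L)
  expect_equal(ex2$cma7, 60 / 70)
  # early refill: carry-over closes the would-be gap
  expect_equal(compute_cma7(data.frame(day = c(0, 20), supply_days = c(30, 30)),
                            window_days = 60)$cma7, 1.0)
  # hospital days covered and supply frozen while admitted
  ex4 <- compute_cma7(data.frame(day = c(0, 50), supply_days = c(30, 30)),
                      hosp = data.frame(admission_day = 30, discharge_day = 40),
                      window_days = 80)
  expect_identical(ex4$covered_days, 70L)
  expect_equal(ex4$cma7, 0.875)
  expect_error(compute_cma7(data.frame(day = 0, supply_days = 30),
                            window_days = 0), "positive")
})

test_that("interval ledger equals the day-grid simulation exactly", {
  set.seed(404)
  for (i in 1:300) {
    e <- random_episode()
    ledger <- compute_cma7(e$events, e$hosp, e$window)
    expect_identical(ledger$covered_days,
                     as.integer(cma7_daygrid(e$events, e$hosp, e$window)))
    expect_gte(ledger$cma7, 0)
    expect_lte(ledger$cma7, 1)
  }
})

test_that("CMA7 is monotone in dispensations and hospitalizations", {
  set.seed(505)
  for (i in 1:60) {
    e <- random_episode()
    base <- compute_cma7(e$events, e$hosp, e$window)$cma7
    extra <- rbind(e$events,
                   data.frame(day = sample(0:(e$window - 1), 1),
                              supply_days = 30L))
    expect_gte(compute_cma7(extra, e$hosp, e$window)$cma7, base)
    add <- sample(0:(e$window - 1), 1)
    hosp2 <- rbind(e$hosp,
                   data.frame(admission_day = add,
                              discharge_day = add + sample(1:30, 1)))
    expect_gte(compute_cma7(e$events, hosp2, e$window)$cma7, base)
  }
})

test_that("a wider gap allowance never converts persistent to discontinued", {
  set.seed(606)
  for (i in 1:80) {
    e <- random_episode()
    s2 <- detect_discontinuation(e$events, e$hosp)$status
    s3 <- detect_discontinuation(e$events, e$hosp, gap_multiplier = 3)$status
    if (s2 == "persistent") expect_identical(s3, "persistent")
  }
})

test_that("vectorized episode engine agrees with the per-episode functions", {
  sim <- simulate_claims(simulation_params(n_patients = 300, seed = 77,
                                           hosp_rate = 1.5))
  ep <- build_episodes(sim$patients[, c("patient_id", "index_date", "group")],
                       sim$dispensing, sim$hospitalizations, sim$deaths)
  disp <- as.data.frame(sim$dispensing)
  hosp <- as.data.frame(sim$hospitalizations)
  tr <- as.data.frame(sim$ground_truth)
  for (pid in sample(ep$patient_id, 60)) {
    events <- disp[disp$patient_id == pid, c("day", "supply_days")]
    h <- hosp[hosp$patient_id == pid, ]
    dd <- tr$death_day[tr$patient_id == pid]
    if (length(dd) == 0L || is.na(dd)) dd <- NA
    single <- detect_discontinuation(events, h, dd)
    row <- ep[ep$patient_id == pid, ]
    expect_identical(row$status, single$status)
    expect_identical(row$censor_day, single$censor_day)
    if (isTRUE(row$eligible)) {
      ref <- compute_cma7(events, h, row$end_day)
      expect_identical(row$covered_days, ref$covered_days)
    }
  }
})

test_that("persistence summary handles degenerate groups and censoring", {
  all100 <- paper_episode_fixture("brand", 50, 0, 0, 0)
  all100$time_to_discontinuation <- 100L
  all100$end_day <- 100L
  s <- persistence_summary(all100)
  expect_equal(s$pct_persistent_183d, 0)

  allp <- data.table::data.table(patient_id = as.character(1:10),
                                 group = "generic", status = "persistent",
                                 time_to_discontinuation = NA_integer_,
                                 end_day = 365L, censor_day = 365L,
                                 eligible = TRUE)
  s2 <- persistence_summary(allp)
  expect_equal(s2$median_time, 365)
})

test_that("implementation classification is closed at the threshold", {
  cm <- data.table::data.table(
    group = "brand", eligible = TRUE,
    cma7 = c(0.90, 0.8999, 0.95, 0.1))
  cl <- classify_implementation(cm)
  expect_equal(cl$n_good, 2L)   # 0.90 exactly is good
  expect_equal(cl$n_poor, 2L)   # 0.8999 is poor
})
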