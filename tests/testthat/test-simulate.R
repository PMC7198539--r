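test_that("marginal brand share is calibrated to its target", {
  p <- simulation_params(n_patients = 1000, brand_share = 0.55, seed = 7)
  sim <- simulate_claims(p)
  frac <- mean(sim$patients$group == "brand")
  se <- sqrt(0.55 * 0.45 / 1000)
  expect_lt(abs(frac - 0.55), 3 * se)
})

test_that("identical seeds give identical bundles, down to one patient", {
  p1 <- simulation_params(n_patients = 1, seed = 1)
  expect_identical(simulate_claims(p1)$patients, simulate_claims(p1)$patients)

  p <- simulation_params(n_patients = 400, seed = 23, switch_rate = 0.1,
                         cortico_rate = 0.05, exclusion_hosp_rate = 0.03)
  a <- simulate_claims(p)
  b <- simulate_claims(p)
  for (tab in c("patients", "dispensing", "hospitalizations", "deaths",
                "ground_truth")) {
    expect_equal(as.data.frame(a[[tab]]), as.data.frame(b[[tab]]))
  }
})

test_that("null assignment model leaves covariates balanced", {
  eff <- default_covariate_effects() * 0
  sim <- simulate_claims(simulation_params(n_patients = 4000,
                                           covariate_effects = eff,
                                           seed = 3))
  pat <- sim$patients
  treated <- pat$group == "brand"
  for (v in list(pat$age, as.numeric(pat$cmu), as.numeric(pat$polypharmacy),
                 as.numeric(pat$fracture_latent))) {
    expect_lt(abs(standardized_difference(v, treated)), 0.1)
  }
})

test_that("stop-day mechanism spans its extremes", {
  # certain stop at day 0: exactly one dispensation each
  sim1 <- simulate_claims(simulation_params(
    n_patients = 50, seed = 2, discontinuation_hazard_brand = 1,
    discontinuation_hazard_generic = 1))
  expect_true(all(table(sim1$dispensing$patient_id) == 1L))

  # no stopping, no jitter, 1-month packages: refills every 30 days to 365
  sim0 <- simulate_claims(simulation_params(
    n_patients = 20, seed = 2,
    discontinuation_hazard_brand = 0, discontinuation_hazard_generic = 0,
    implementation_classes = FALSE,
    refill_delay = dist_spec("constant", value = 0),
    package_mix = 0, death_rate = 0, hosp_rate = 0))
  days <- sort(unique(sim0$dispensing$day))
  expect_identical(days, seq(0L, 360L, by = 30L))
  expect_true(all(table(sim0$dispensing$patient_id) == 13L))
})

test_that("a higher brand stop hazard lowers observed brand persistence", {
  sim <- simulate_claims(simulation_params(
    n_patients = 5000, seed = 9,
    discontinuation_hazard_brand = 0.006,
    discontinuation_hazard_generic = 0.002))
  ep <- build_episodes(sim$patients[, c("patient_id", "index_date", "group")],
                       sim$dispensing, sim$hospitalizations, sim$deaths)
  ps <- persistence_summary(ep)
  expect_lt(ps$pct_persistent_365d[ps$group == "brand"],
            ps$pct_persistent_365d[ps$group == "generic"])
})

test_that("hospitalization generation follows its rate and duration spec", {
  none <- simulate_claims(simulation_params(n_patients = 100, seed = 4,
                                            hosp_rate = 0))
  expect_identical(nrow(none$hospitalizations[none$hospitalizations$admission_day >= 0]),
                   0L)

  fixed <- simulate_claims(simulation_params(
    n_patients = 300, seed = 4, death_rate = 0, hosp_rate = 0.5,
    hosp_duration = dist_spec("constant", value = 5)))
  inwin <- fixed$hospitalizations[fixed$hospitalizations$admission_day >= 0, ]
  expect_true(all(inwin$discharge_day - inwin$admission_day <= 5))
  expect_true(any(inwin$discharge_day - inwin$admission_day == 5))

  pois <- simulate_claims(simulation_params(n_patients = 2000, seed = 8,
                                            death_rate = 0, hosp_rate = 1))
  counts <- table(factor(pois$hospitalizations$patient_id[
    pois$hospitalizations$admission_day >= 0],
    levels = pois$patients$patient_id))
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / 2000))
})

test_that("ground truth is complete and consistent with emitted claims", {
  p <- simulation_params(n_patients = 500, seed = 31)
  sim <- simulate_claims(p)
  tr <- sim$ground_truth
  expect_identical(nrow(tr), 500L)
  # truth group agrees with the emitted brand flag on every dispensation
  m <- merge(sim$dispensing, tr, by = "patient_id")
  expect_true(all(m$brand == (m$group == "brand")))
  # no dispensation after the death day, none outside the study window
  md <- merge(sim$dispensing, tr[!is.na(tr$death_day)], by = "patient_id")
  expect_true(all(md$day < md$death_day))
  expect_true(all(sim$dispensing$day >= 0 & sim$dispensing$day < 365))
})

test_that("claims round-trip through files, truth export included", {
  dir <- withr::local_tempdir()
  p <- simulation_params(n_patients = 80, seed = 12)
  sim <- simulate_claims(p)
  paths <- write_claims(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_claims(dir)
  expect_equal(nrow(back$patients), 80L)
  expect_equal(nrow(back$dispensing), nrow(sim$dispensing))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_rr, 0.90)
  expect_equal(nrow(truth$patients), 80L)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(simulation_params(brand_share = 1.2), "brand_share")
  expect_error(simulation_params(discontinuation_hazard_brand = -0.1),
               "discontinuation_hazard_brand")
  expect_error(simulation_params(refill_delay = list(family = "uniform_int")),
               "refill_delay")
  expect_error(dist_spec("uniform_int", min = 5, max = 1), "uniform_int")
  expect_error(simulation_params(p_good_generic = 0.9,
                                 good_implementation_rr = 1.2),
               "good_implementation_rr")
})
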