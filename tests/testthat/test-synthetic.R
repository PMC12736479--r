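test_that("configuration is validated", {
  expect_error(sim_config(chronic_n_range = c(3L, 6L)), "contradictory")
  expect_error(sim_config(injection_rates = c(NOT_A_PATTERN = 0.5)),
               "unknown injection pattern")
  expect_error(sim_config(sex_male_prob = 1.4))
})

test_that("generation is empty at n = 0 and deterministic in the seed", {
  empty <- generate_claims(sim_config(n_patients = 0L, seed = 1L))
  expect_equal(nrow(empty$records), 0L)
  expect_equal(nrow(empty$deaths), 0L)
  expect_equal(nrow(empty$truth$events), 0L)

  a <- generate_claims(sim_config(n_patients = 120L, seed = 1L))
  b <- generate_claims(sim_config(n_patients = 120L, seed = 1L))
  c <- generate_claims(sim_config(n_patients = 120L, seed = 2L))
  expect_identical(a$records, b$records)
  expect_identical(a$deaths, b$deaths)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$records, c$records))
})

test_that("demographics hit the configured sex and age structure", {
  set.seed(10)
  allf <- sample_demographics(sim_config(n_patients = 200L,
                                         sex_male_prob = 0))
  expect_true(all(allf$sex == "F"))

  set.seed(10)
  demo <- sample_demographics(sim_config(n_patients = 10000L))
  share <- mean(demo$sex == "M")
  expect_gt(share, 0.38); expect_lt(share, 0.42)   # 2-SE binomial band

  age <- age_at(demo$birth_date, rep(study_window()$end, nrow(demo)))
  expect_true(all(age >= 65 & age <= 100))
  expect_gt(stats::median(age), 72); expect_lt(stats::median(age), 82)

  dead <- generate_claims(sim_config(n_patients = 60L, seed = 3L,
                                     mortality_prob = 1))
  expect_equal(nrow(build_cohort(dead$records, dead$deaths)$patients), 0L)
  expect_equal(nrow(dead$truth$events), 0L)
})

test_that("a single injected pattern is recovered exactly and exclusively", {
  cfg <- sim_config(n_patients = 400L, seed = 5L, mortality_prob = 0,
                    injection_rates = c(PPI_LONG_TERM = 1.0))
  sim <- generate_claims(cfg)
  cohort <- build_cohort(sim$records, sim$deaths)
  expect_equal(nrow(cohort$patients), 400L)
  ev <- detect_all(cohort, sim$records)
  expect_equal(nrow(ev), 400L)
  expect_true(all(ev$rule_id == "ppi_over_8_weeks"))
  expect_setequal(ev$patient_id, cohort$patients$patient_id)
})

test_that("sub-threshold control patterns are never detected", {
  cfg <- sim_config(n_patients = 250L, seed = 6L, mortality_prob = 0,
                    injection_rates = c(PPI_SHORT_GAP = 1.0,
                                        NSAID_SUBCHRONIC = 1.0))
  sim <- generate_claims(cfg)
  expect_equal(nrow(sim$truth$events), 0L)
  ev <- detect_all(build_cohort(sim$records, sim$deaths), sim$records)
  expect_equal(nrow(ev), 0L)
})

test_that("ground truth is confirmed by the independent brute-force oracle", {
  cfg <- sim_config(n_patients = 60L, seed = 9L,
                    injection_rates = c(PPI_LONG_TERM = 0.4,
                                        PAROXETINE_CHRONIC = 0.25,
                                        TICLOPIDINE = 0.1,
                                        SULFONYLUREA = 0.15,
                                        FUROSEMIDE = 0.3,
                                        CO_DISPENSING_PAIR = 0.2,
                                        MULTI_ANTICHOLINERGIC = 0.1))
  sim <- generate_claims(cfg)
  cohort <- build_cohort(sim$records, sim$deaths)
  expect_equal(brute_force_detect(cohort, sim$records, default_catalog()),
               sim$truth$events)
})

test_that("multi-anticholinergic patients carry the expected ACB burden", {
  cfg <- sim_config(n_patients = 30L, seed = 12L, mortality_prob = 0,
                    injection_rates = c(MULTI_ANTICHOLINERGIC = 1.0),
                    multi_achol_k = 3L)
  sim <- generate_claims(cfg)
  expect_equal(nrow(sim$truth$chronic), 30L)
  expect_true(all(sim$truth$chronic$acb_total == 9L))
  expect_true(all(sim$truth$chronic$agents == "G04BD04;N06AA09;N06AB05"))
  expect_true(all(sim$truth$chronic$year == 2021L))
})

test_that("simulations round-trip through the claims files", {
  dir <- withr::local_tempdir()
  sim <- generate_claims(sim_config(n_patients = 40L, seed = 4L))
  paths <- write_simulation(sim, dir)
  back <- read_dispensing(paths[1])
  attr(back, "errors") <- NULL
  expect_equal(back, sim$records)
  expect_equal(read_deaths(paths[2]), sim$deaths)
  gt <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_equal(if (is.null(nrow(gt$events))) 0L else nrow(gt$events),
               nrow(sim$truth$events))
})
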