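test_that("gap screening flags consecutive dispensations in (56, 180] days", {
  hit <- duration_over_8_weeks(as.Date(c("2019-01-01", "2019-03-15")))  # 73
  expect_true(as.logical(hit))
  expect_equal(attr(hit, "pairs")$to, as.Date("2019-03-15"))

  expect_false(as.logical(duration_over_8_weeks(as.Date("2019-01-01"))))
  expect_false(as.logical(duration_over_8_weeks(as.Date(character(0)))))
  # gaps 29 and 305: neither in (56, 180]
  expect_false(as.logical(duration_over_8_weeks(
    as.Date(c("2019-01-01", "2019-01-30", "2019-12-01")))))
  # boundary: 56 is out (strict lower), 180 is in (inclusive upper)
  expect_false(as.logical(duration_over_8_weeks(
    as.Date(c("2019-01-01", "2019-01-01")) + c(0, 56))))
  expect_true(as.logical(duration_over_8_weeks(
    as.Date(c("2019-01-01", "2019-01-01")) + c(0, 180))))
})

test_that("co-dispensing uses a 90-day window over all date pairs", {
  expect_true(as.logical(co_dispensed(as.Date("2019-01-01"),
                                      as.Date("2019-02-15"))))   # 44 days
  expect_false(as.logical(co_dispensed(as.Date("2019-01-01"),
                                       as.Date("2019-06-01"))))  # 151 days
  res <- co_dispensed(as.Date(c("2019-01-01", "2019-07-01")),
                      as.Date("2019-07-10"))                     # second A date
  expect_true(as.logical(res))
  expect_equal(attr(res, "pairs")$a, as.Date("2019-07-01"))
  expect_true(as.logical(co_dispensed(as.Date("2019-01-01"),
                                      as.Date("2019-04-01"))))   # 90: inclusive
})

test_that("chronic use needs 5+ distinct dispensing dates in the year", {
  d5 <- as.Date("2021-01-10") + (0:4) * 30
  expect_true(chronic_in_year(d5, 2021L))
  expect_false(chronic_in_year(d5[1:4], 2021L))
  # same-day duplicates collapse
  expect_false(chronic_in_year(c(d5[1:4], d5[4]), 2021L))
  d33 <- c(as.Date("2020-06-01") + (0:2) * 10, as.Date("2021-06-01") + (0:2) * 10)
  expect_false(chronic_in_year(d33, 2020L))
  expect_false(chronic_in_year(d33, 2021L))
})

test_that("unit-dose limits compare strictly and flag missing doses", {
  asa <- make_records("P1", "2019-01-01", "B01AC06",
                      medication_name = "ASPIRIN TABS", unit_dose_mg = 500)
  expect_true(unit_dose_exceeds(asa, 325))
  asa$unit_dose_mg <- 325
  expect_false(unit_dose_exceeds(asa, 325))
  asa$unit_dose_mg <- NA_real_
  expect_true(is.na(unit_dose_exceeds(asa, 325)))
  # falls back to the name when the column is missing
  asa$medication_name <- "ASPIRIN 500MG TABS"
  expect_true(unit_dose_exceeds(asa, 325))
})

test_that("route/form keywords and strengths parse from medication names", {
  rf <- parse_route_form(c("PANTOPRAZOLE 40MG TABS", "DICLOFENAC CREAM 1%",
                           "XYZ 10", "DIAZEPAM 5MG SOLUZ IV FL",
                           "FENTANYL CEROTTO 25", "GLYCERIN SUPP"))
  expect_equal(rf$route, c("ORAL", "TOPICAL", "UNKNOWN", "PARENTERAL",
                           "TRANSDERMAL", "RECTAL"))
  expect_equal(rf$form, c("TABLET", "CREAM", "UNKNOWN", "SOLUTION",
                          "PATCH", "SUPPOSITORY"))

  expect_equal(parse_strength(c("ASA 500MG TABS", "METFORMIN 1G",
                                "INSULIN 100IU/ML", "XY 2,5 MG CPR")),
               c(500, 1000, NA, 2.5))
  # IVABRADINE must not token-match the IV keyword
  expect_equal(parse_route_form("IVABRADINE 5MG CPR")$route, "ORAL")
})

test_that("evaluate_rule emits events only when the condition holds in-year", {
  cat <- default_catalog()
  paro <- make_records("P1", "2020-04-01", "N06AB05",
                       medication_name = "PAROXETINE 20MG TABS")
  ev <- evaluate_rule(paro, cat$rules[["paroxetine"]], 2020L, cat)
  expect_equal(ev$category, "AVOID")
  expect_equal(ev$year, 2020L)
  expect_null(evaluate_rule(paro, cat$rules[["paroxetine"]], 2019L, cat))

  ppi2 <- make_records("P1", c("2020-01-01", "2020-03-15"), "A02BC02")
  expect_equal(evaluate_rule(ppi2, cat$rules[["ppi_over_8_weeks"]], 2020L,
                             cat)$rule_id, "ppi_over_8_weeks")
  ppi1 <- make_records("P1", "2020-01-01", "A02BC02")
  expect_null(evaluate_rule(ppi1, cat$rules[["ppi_over_8_weeks"]], 2020L, cat))

  # indeterminate dose: skip, not an event
  asa <- make_records("P1", "2020-01-01", "B01AC06",
                      medication_name = "ASPIRIN TABS")
  expect_s3_class(evaluate_rule(asa, cat$rules[["aspirin_high_dose"]], 2020L,
                                cat), "pim_rule_skip")
})

test_that("detect_all collapses to one event per patient-rule-year", {
  cat <- default_catalog()
  expect_equal(nrow(detect_all(build_cohort(make_records(character(0),
                                                         character(0),
                                                         character(0))),
                               make_records(character(0), character(0),
                                            character(0)), cat)), 0L)

  ticlo <- make_records("P1", as.Date("2019-02-01") + (0:5) * 45, "B01AC05",
                        medication_name = "TICLOPIDINE 250MG TABS")
  ticlo$dispense_date[ticlo$dispense_date > as.Date("2019-12-31")] <-
    as.Date("2019-12-20")
  cohort <- build_cohort(ticlo)
  ev <- detect_all(cohort, ticlo, cat)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$rule_id, "ticlopidine")
  expect_equal(ev$year, 2019L)
  expect_equal(ev$n_triggers, 6L)
  expect_equal(sort(unlist(ev$triggers)), 1:6)
})

test_that("detection is idempotent under row duplication", {
  for (seed in c(3, 17)) {
    rec <- random_micro_cohort(seed)
    cohort <- build_cohort(rec)
    ev1 <- detect_all(cohort, rec)
    doubled <- rbind(rec, rec)
    ev2 <- detect_all(build_cohort(doubled), doubled)
    cols <- c("patient_id", "year", "rule_id", "category", "label")
    expect_equal(ev2[, cols], ev1[, cols])
  }
})

test_that("adding dispensations never removes ALWAYS/DURATION/CO events", {
  set.seed(5)
  for (seed in c(8, 21, 34)) {
    rec <- random_micro_cohort(seed)
    cohort <- build_cohort(rec)
    ev1 <- detect_all(cohort, rec)
    keep <- ev1$rule_id %in% c("paroxetine", "ticlopidine", "furosemide",
                               "ppi_over_8_weeks", "nsaid_anticoagulant",
                               "sulfonylureas", "tricyclic_antidepressants")
    extra <- make_records(rec$patient_id[1], "2019-06-15", "N02BE01",
                          birth_date = as.character(rec$birth_date[1]))
    rec2 <- rbind(rec, extra)
    ev2 <- detect_all(build_cohort(rec2), rec2)
    key <- function(e) paste(e$patient_id, e$year, e$rule_id)
    expect_true(all(key(ev1[keep, ]) %in% key(ev2)))
  }
})

test_that("detect_all matches the brute-force oracle on random cohorts", {
  cat <- default_catalog()
  for (seed in seq(0, 45, by = 5)) {
    rec <- random_micro_cohort(seed)
    cohort <- build_cohort(rec)
    got <- detect_all(cohort, rec, cat)[, c("patient_id", "year", "rule_id",
                                            "category")]
    rownames(got) <- NULL
    expect_equal(got, brute_force_detect(cohort, rec, cat), info = seed)
  }
})
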