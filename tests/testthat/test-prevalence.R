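test_that("percentages round half-up at one decimal", {
  expect_equal(percent(65807, 115962), 56.7)
  expect_equal(percent(0, 10), 0.0)
  expect_equal(percent(1738, 2368), 73.4)
  expect_equal(percent(1, 8), 12.5)       # exact .x5 rounds up
  expect_equal(percent(1, 16, 2), 6.25)
  expect_error(percent(1, 0), "denominator")
  expect_error(percent(5, 4), "numerator")
})

fake_cohort <- function(denoms, window = study_window()) {
  ids <- unique(unlist(denoms))
  structure(list(
    window = window,
    patients = data.frame(patient_id = ids,
                          birth_date = as.Date("1945-01-01"),
                          sex = rep("F", length(ids)),
                          death_date = as.Date(NA),
                          age = rep(76L, length(ids)),
                          age_group = age_group(rep(76L, length(ids)))),
    yearly_denominators = denoms), class = "pim_cohort")
}

fake_events <- function(patient_id, year, category = "AVOID",
                        rule_id = "paroxetine", label = "Paroxetine",
                        n_triggers = 1L) {
  data.frame(patient_id = patient_id, year = year,
             rule_id = rep_len(rule_id, length(patient_id)),
             category = rep_len(category, length(patient_id)),
             label = rep_len(label, length(patient_id)),
             n_triggers = rep_len(n_triggers, length(patient_id)),
             first_trigger_date = as.Date(sprintf("%d-06-01", year)),
             stringsAsFactors = FALSE)
}

test_that("annual prevalence divides distinct PIM patients by yearly users", {
  denoms <- list("2018" = c("A", "B"), "2019" = c("A", "B", "C", "D"),
                 "2020" = "A", "2021" = c("A", "B"))
  cohort <- fake_cohort(denoms)

  cells <- annual_prevalence(fake_events(character(0), integer(0)), cohort)
  expect_true(all(cells$numerator == 0L))
  expect_true(all(cells$percent[cells$denominator > 0] == 0.0))

  ev <- fake_events("A", 2019L)
  cells <- annual_prevalence(ev, cohort)
  expect_equal(cells$percent[cells$period == "2019"], 25.0)
  expect_equal(cells$percent[cells$period == "2020"], 0.0)
  expect_equal(cells$numerator[cells$period == "total"], 1L)
  expect_equal(cells$denominator[cells$period == "total"], 4L)

  # a patient with events under two categories counts once overall
  ev2 <- rbind(fake_events(c("A", "A"), c(2019L, 2019L),
                           category = c("AVOID", "ANTICHOLINERGIC")))
  expect_equal(annual_prevalence(ev2, cohort)$numerator[2], 1L)
  expect_equal(annual_prevalence(ev2, cohort,
                                 "ANTICHOLINERGIC")$numerator[2], 1L)
})

test_that("injected 50% PIM rate is recovered within 3 points at n = 2000", {
  cfg <- sim_config(n_patients = 2000L, seed = 1L, mortality_prob = 0,
                    injection_rates = c(PPI_LONG_TERM = 0.5))
  sim <- generate_claims(cfg)
  scr <- pim_screen(sim$records, sim$deaths)
  total <- scr$prevalence[scr$prevalence$stratum == "all" &
                            scr$prevalence$period == "total", ]
  expect_lt(abs(total$percent - 50), 3)
})

test_that("PIM ranks order groups by distinct patients with label ties", {
  ev <- fake_events("A", 2020L, label = "PPI", rule_id = "ppi_over_8_weeks")
  r <- rank_pims(ev, 2020L, "AVOID")
  expect_equal(r$label, "PPI")
  expect_equal(r$percent, 100.0)

  mk <- function(lab, n) fake_events(sprintf("%s%03d", lab, 1:n), 2020L,
                                     label = lab, rule_id = lab)
  ev2 <- rbind(mk("PPI", 87), mk("Paro", 8), mk("SU", 5))
  r2 <- rank_pims(ev2, 2020L, "AVOID")
  expect_equal(r2$label, c("PPI", "Paro", "SU"))
  expect_equal(r2$n_patients, c(87L, 8L, 5L))
  expect_equal(r2$percent, c(87.0, 8.0, 5.0))
  expect_equal(r2$rank, 1:3)

  tie <- rbind(mk("B", 3), mk("A", 3))
  expect_equal(rank_pims(tie, 2020L, "AVOID")$label, c("A", "B"))

  # top_k cut and inclusion threshold
  many <- do.call(rbind, lapply(1:8, function(i) mk(sprintf("L%02d", i), i)))
  expect_equal(nrow(rank_pims(many, 2020L, "AVOID", top_k = 6L)), 6L)
  r3 <- rank_pims(many, 2020L, "AVOID", min_percent = 2)
  expect_true(all(r3$percent > 2))
})

test_that("ATC level-4 grouping truncates to 5 characters", {
  expect_equal(group_atc_level4(c("C03CA01", "A02BC02", "N06AB05")),
               c("C03CA", "A02BC", "N06AB"))
  expect_warning(out <- group_atc_level4("A02BC"), "unchanged")
  expect_equal(out, "A02BC")
})

test_that("sample summary reports interpolated medians and IQRs", {
  denoms <- list("2018" = character(0), "2019" = c("A", "B", "C"),
                 "2020" = character(0), "2021" = character(0))
  cohort <- fake_cohort(denoms)
  cohort$patients$age <- c(70L, 76L, 82L)
  ev <- fake_events(c("A", "B", "C"), 2019L, n_triggers = c(6L, 7L, 8L))
  s <- summarize_sample(cohort, ev)
  row <- s[s$period == "2019", ]
  expect_equal(row$age_median, 76)
  expect_equal(row$age_q1, 73.0)
  expect_equal(row$age_q3, 79.0)
  expect_equal(row$pims_median, 7)
  expect_equal(row$n_patients, 3L)

  one <- summarize_sample(cohort, ev[1, , drop = FALSE])
  row1 <- one[one$period == "2019", ]
  expect_equal(row1$age_median, row1$age_q1)
  expect_equal(row1$age_median, row1$age_q3)
  expect_equal(row1$pims_median, 6)
})
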