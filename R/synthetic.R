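# Seeded synthetic dispensing-claims generator with exact ground-truth PIM
# labels. The generator emulates the structure the screening assumes:
# an older-adult population (ages 65-100, median near 77, ~40% male)
# observed over a four-year window, background dispensing of non-catalog
# drugs, and per-patient injected PIM patterns whose placed dates satisfy
# the corresponding rule conditions by construction. A single seeded RNG
# stream with a fixed draw order (demographics first, then per-patient
# dispensing in patient order) makes outputs reproducible.

INJECTION_PATTERNS <- c("PPI_LONG_TERM", "PAROXETINE_CHRONIC", "SULFONYLUREA",
                        "TICLOPIDINE", "FUROSEMIDE", "CO_DISPENSING_PAIR",
                        "MULTI_ANTICHOLINERGIC",
                        # specificity controls: sub-threshold by design
                        "PPI_SHORT_GAP", "NSAID_SUBCHRONIC")

#' Simulation configuration
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed for the single RNG stream.
#' @param window A [study_window()].
#' @param sex_male_prob Probability of male sex (default 0.40).
#' @param age_mode Mode of the triangular age-at-window-end distribution on
#'   65-100; the default 70 puts the median near 77.
#' @param mortality_prob Probability of a death date inside the window
#'   (such patients are excluded by [build_cohort()], exercising the
#'   exclusion path).
#' @param injection_rates Named per-patient probabilities for the PIM
#'   patterns `PPI_LONG_TERM`, `PAROXETINE_CHRONIC`, `SULFONYLUREA`,
#'   `TICLOPIDINE`, `FUROSEMIDE`, `CO_DISPENSING_PAIR`,
#'   `MULTI_ANTICHOLINERGIC`, plus the sub-threshold specificity controls
#'   `PPI_SHORT_GAP` (gap <= 56 days) and `NSAID_SUBCHRONIC` (4
#'   dispensations/year). Unnamed patterns default to 0.
#' @param multi_achol_k Number of distinct strong-anticholinergic agents
#'   placed by `MULTI_ANTICHOLINERGIC` (default 3).
#' @param chronic_n_range Range (min >= 5) of dispensations per year for
#'   chronic patterns.
#' @return A validated `"sim_config"` object.
#' @export
sim_config <- function(n_patients = 1000L, seed = 1L,
                       window = study_window(),
                       sex_male_prob = 0.40, age_mode = 70,
                       mortality_prob = 0.05,
                       injection_rates = c(PPI_LONG_TERM = 0.45,
                                           PAROXETINE_CHRONIC = 0.05,
                                           SULFONYLUREA = 0.04,
                                           TICLOPIDINE = 0.015,
                                           FUROSEMIDE = 0.30,
                                           CO_DISPENSING_PAIR = 0.02,
                                           MULTI_ANTICHOLINERGIC = 0.002),
                       multi_achol_k = 3L,
                       chronic_n_range = c(5L, 8L)) {
  rates <- stats::setNames(rep(0, length(INJECTION_PATTERNS)),
                           INJECTION_PATTERNS)
  unknown <- setdiff(names(injection_rates), INJECTION_PATTERNS)
  if (length(unknown) > 0L) {
    stop("unknown injection pattern(s): ", paste(unknown, collapse = ", "))
  }
  rates[names(injection_rates)] <- injection_rates
  stopifnot(n_patients >= 0, inherits(window, "study_window"),
            sex_male_prob >= 0, sex_male_prob <= 1,
            mortality_prob >= 0, mortality_prob <= 1,
            age_mode >= 65, age_mode <= 100,
            all(rates >= 0), all(rates <= 1))
  if (chronic_n_range[1L] < 5L) {
    stop("contradictory config: chronic patterns need at least 5 ",
         "dispensations per year")
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 window = window, sex_male_prob = sex_male_prob,
                 age_mode = age_mode, mortality_prob = mortality_prob,
                 injection_rates = rates,
                 multi_achol_k = as.integer(multi_achol_k),
                 chronic_n_range = as.integer(chronic_n_range)),
            class = "sim_config")
}

# inverse-CDF draw from a triangular(65, age_mode, 100) distribution
triangular_age <- function(u, mode) {
  a <- 65; b <- 100; cc <- mode
  fc <- (cc - a) / (b - a)
  ifelse(u < fc, a + sqrt(u * (b - a) * (cc - a)),
         b - sqrt((1 - u) * (b - a) * (b - cc)))
}

#' Sample the synthetic patient roster
#'
#' Draws sex (Bernoulli, `sex_male_prob`), age at window end (triangular on
#' 65-100), a birth date consistent with that completed age, and an
#' optional in-window death date. Uses (and advances) the current RNG
#' stream; [generate_claims()] calls this first.
#'
#' @param config A [sim_config()].
#' @return Data frame: `patient_id`, `birth_date`, `sex`, `death_date`.
#' @export
sample_demographics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  end <- config$window$end
  if (n == 0L) {
    return(data.frame(patient_id = character(0),
                      birth_date = as.Date(character(0)),
                      sex = character(0),
                      death_date = as.Date(character(0))))
  }
  sex <- ifelse(stats::runif(n) < config$sex_male_prob, "M", "F")
  age <- floor(triangular_age(stats::runif(n), config$age_mode))
  extra <- sample.int(365L, n, replace = TRUE) - 1L
  anniversary <- as.Date(sprintf("%d-%s", year_of(end) - age,
                                 format(end, "%m-%d")))
  birth <- anniversary - extra
  dead <- stats::runif(n) < config$mortality_prob
  span <- as.integer(end - config$window$start)
  death <- as.Date(rep(NA, n))
  death[dead] <- config$window$start +
    sample.int(span + 1L, sum(dead), replace = TRUE) - 1L
  data.frame(patient_id = sprintf("P%06d", seq_len(n)),
             birth_date = birth, sex = sex, death_date = death,
             stringsAsFactors = FALSE)
}

sim_drug <- function(atc, name, dose) {
  list(atc = atc, name = name, dose = dose)
}

SIM_BACKGROUND_MENU <- list(
  sim_drug("N02BE01", "PARACETAMOL 500MG TABS", 500),
  sim_drug("A10BA02", "METFORMIN 1G TABS", 1000),
  sim_drug("C09AA05", "RAMIPRIL 5MG TABS", 5),
  sim_drug("C10AA05", "ATORVASTATIN 20MG TABS", 20),
  sim_drug("J01CA04", "AMOXICILLIN 1G TABS", 1000)
)
SIM_BACKGROUND_RATES <- c(1.2, 1.0, 1.0, 0.8, 0.3)  # Poisson, per year

SIM_ACHOL_POOL <- list(
  sim_drug("N06AB05", "PAROXETINE 20MG TABS", 20),
  sim_drug("N06AA09", "AMITRIPTYLINE 25MG TABS", 25),
  sim_drug("G04BD04", "OXYBUTYNIN 5MG TABS", 5),
  sim_drug("N05AH03", "OLANZAPINE 5MG TABS", 5),
  sim_drug("N06AA04", "CLOMIPRAMINE 25MG TABS", 25)
)

year_start <- function(y) as.Date(sprintf("%d-01-01", y))

# ~monthly spacing with jitter, staying inside the calendar year
monthly_dates <- function(y, k) {
  start <- sample.int(40L, 1L)
  gaps <- if (k > 1L) 25L + sample.int(11L, k - 1L, replace = TRUE) - 1L
          else integer(0)
  year_start(y) + (start + cumsum(c(0L, gaps))) - 1L
}

random_dates <- function(y, k) {
  sort(year_start(y) + sample.int(365L, k) - 1L)
}

#' Generate a synthetic claims dataset with ground truth
#'
#' Deterministic for a fixed seed. Every injected pattern places
#' dispensation dates that satisfy the corresponding rule condition by
#' construction (e.g. `PPI_LONG_TERM` places two dates 60-170 days apart
#' within one year; chronic patterns place at least 5 dates in one year;
#' `CO_DISPENSING_PAIR` places an NSAID and a vitamin K antagonist within
#' 90 days); the specificity-control patterns place sub-threshold dates
#' that must never be detected. Non-injected dispensing uses only
#' non-catalog drugs. Ground truth (the expected PIM events and chronic
#' anticholinergic users of every eligible patient) is computed from the
#' placed dates with the package's condition predicates, and is
#' independently cross-checked against a brute-force evaluator in the test
#' suite.
#'
#' @param config A [sim_config()].
#' @param catalog Catalog used to derive ground-truth labels.
#' @return A `"pim_simulation"` list: `records`, `deaths`, `truth` (list
#'   with `events` and `chronic` data frames), and `config`.
#' @export
generate_claims <- function(config, catalog = default_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  window <- config$window
  years <- window$years
  demo <- sample_demographics(config)

  rows <- list()
  emit <- function(pid, drug, dates) {
    if (length(dates) == 0L) return(NULL)
    dates <- dates[dates >= window$start & dates <= window$end]
    if (length(dates) == 0L) return(NULL)
    data.frame(patient_id = pid, dispense_date = dates, atc_code = drug$atc,
               medication_name = drug$name,
               n_packages = sample(1:2, length(dates), replace = TRUE),
               unit_dose_mg = drug$dose, stringsAsFactors = FALSE)
  }

  lo <- config$chronic_n_range[1L]; hi <- config$chronic_n_range[2L]
  chronic_k <- function() sample(seq.int(lo, hi), 1L)

  for (i in seq_len(config$n_patients)) {
    pid <- demo$patient_id[i]
    # background, non-catalog drugs
    for (j in seq_along(SIM_BACKGROUND_MENU)) {
      for (y in years) {
        k <- stats::rpois(1L, SIM_BACKGROUND_RATES[j])
        if (k > 0L) {
          rows[[length(rows) + 1L]] <-
            emit(pid, SIM_BACKGROUND_MENU[[j]], random_dates(y, min(k, 20L)))
        }
      }
    }
    inject <- stats::runif(length(INJECTION_PATTERNS)) <
      config$injection_rates[INJECTION_PATTERNS]
    names(inject) <- INJECTION_PATTERNS
    if (inject[["PPI_LONG_TERM"]]) {
      y <- sample(years, 1L)
      d1 <- year_start(y) + sample.int(150L, 1L) - 1L
      d2 <- d1 + sample(60:170, 1L)
      rows[[length(rows) + 1L]] <-
        emit(pid, sim_drug("A02BC02", "PANTOPRAZOLE 40MG TABS", 40), c(d1, d2))
    }
    if (inject[["PPI_SHORT_GAP"]]) {
      y <- sample(years, 1L)
      d1 <- year_start(y) + sample.int(150L, 1L) - 1L
      d2 <- d1 + sample(20:56, 1L)
      rows[[length(rows) + 1L]] <-
        emit(pid, sim_drug("A02BC02", "PANTOPRAZOLE 40MG TABS", 40), c(d1, d2))
    }
    if (inject[["PAROXETINE_CHRONIC"]]) {
      y <- sample(years, 1L)
      rows[[length(rows) + 1L]] <-
        emit(pid, sim_drug("N06AB05", "PAROXETINE 20MG TABS", 20),
             monthly_dates(y, chronic_k()))
    }
    if (inject[["SULFONYLUREA"]]) {
      y <- sample(years, 1L)
      rows[[length(rows) + 1L]] <-
        emit(pid, sim_drug("A10BB01", "GLIBENCLAMIDE 5MG TABS", 5),
             random_dates(y, sample.int(3L, 1L)))
    }
    if (inject[["TICLOPIDINE"]]) {
      y <- sample(years, 1L)
      rows[[length(rows) + 1L]] <-
        emit(pid, sim_drug("B01AC05", "TICLOPIDINE 250MG TABS", 250),
             random_dates(y, sample(4:8, 1L)))
    }
    if (inject[["FUROSEMIDE"]]) {
      y <- sample(years, 1L)
      rows[[length(rows) + 1L]] <-
        emit(pid, sim_drug("C03CA01", "FUROSEMIDE 25MG TABS", 25),
             random_dates(y, sample.int(4L, 1L)))
    }
    if (inject[["CO_DISPENSING_PAIR"]]) {
      y <- sample(years, 1L)
      a <- year_start(y) + sample.int(270L, 1L) - 1L
      b <- a + sample(0:80, 1L)
      rows[[length(rows) + 1L]] <-
        emit(pid, sim_drug("M01AB05", "DICLOFENAC 50MG TABS", 50), a)
      rows[[length(rows) + 1L]] <-
        emit(pid, sim_drug("B01AA03", "WARFARIN 5MG TABS", 5), b)
    }
    if (inject[["NSAID_SUBCHRONIC"]]) {
      y <- sample(years, 1L)
      rows[[length(rows) + 1L]] <-
        emit(pid, sim_drug("M01AB05", "DICLOFENAC 50MG TABS", 50),
             monthly_dates(y, 4L))
    }
    if (inject[["MULTI_ANTICHOLINERGIC"]]) {
      y <- years[length(years)]
      for (drug in SIM_ACHOL_POOL[seq_len(min(config$multi_achol_k,
                                              length(SIM_ACHOL_POOL)))]) {
        rows[[length(rows) + 1L]] <- emit(pid, drug, monthly_dates(y, chronic_k()))
      }
    }
  }

  records <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(patient_id = character(0),
               dispense_date = as.Date(character(0)), atc_code = character(0),
               medication_name = character(0), n_packages = integer(0),
               unit_dose_mg = numeric(0), stringsAsFactors = FALSE)
  if (nrow(records) > 0L) {
    records$birth_date <- demo$birth_date[match(records$patient_id,
                                                demo$patient_id)]
    records$sex <- demo$sex[match(records$patient_id, demo$patient_id)]
    records <- records[order(records$patient_id, records$dispense_date,
                             records$atc_code, method = "radix"), ,
                       drop = FALSE]
    records <- records[, c("patient_id", "birth_date", "sex", "dispense_date",
                           "atc_code", "medication_name", "n_packages",
                           "unit_dose_mg")]
    rownames(records) <- NULL
  } else {
    records <- data.frame(patient_id = character(0),
                          birth_date = as.Date(character(0)),
                          sex = character(0),
                          dispense_date = as.Date(character(0)),
                          atc_code = character(0),
                          medication_name = character(0),
                          n_packages = integer(0), unit_dose_mg = numeric(0),
                          stringsAsFactors = FALSE)
  }
  deaths <- demo[!is.na(demo$death_date), c("patient_id", "death_date"),
                 drop = FALSE]
  rownames(deaths) <- NULL

  truth <- compute_ground_truth(records, deaths, window, catalog)
  structure(list(records = records, deaths = deaths, truth = truth,
                 config = config),
            class = "pim_simulation")
}

# Expected labels for every eligible patient, from the placed dates, via
# the shared condition predicates (evaluate_rule / chronic predicates).
compute_ground_truth <- function(records, deaths, window, catalog) {
  cohort <- build_cohort(records, deaths, window)
  ev_rows <- list()
  chron_rows <- list()
  by_patient <- split(seq_len(nrow(records)), records$patient_id)
  for (pid in cohort$patients$patient_id) {
    hist <- records[by_patient[[pid]], , drop = FALSE]
    for (rid in names(catalog$rules)) {
      rule <- catalog$rules[[rid]]
      for (y in window$years) {
        ev <- evaluate_rule(hist, rule, y, catalog)
        if (!is.null(ev) && !inherits(ev, "pim_rule_skip")) {
          ev_rows[[length(ev_rows) + 1L]] <-
            data.frame(patient_id = pid, year = y, rule_id = rid,
                       category = rule$category, stringsAsFactors = FALSE)
        }
      }
    }
    for (y in window$years) {
      agents <- chronic_anticholinergics(hist, y, catalog)
      if (length(agents) > 0L) {
        chron_rows[[length(chron_rows) + 1L]] <-
          data.frame(patient_id = pid, year = y,
                     agents = paste(agents, collapse = ";"),
                     acb_total = acb_total(agents, catalog),
                     stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(ev_rows) > 0L) do.call(rbind, ev_rows) else
    data.frame(patient_id = character(0), year = integer(0),
               rule_id = character(0), category = character(0),
               stringsAsFactors = FALSE)
  if (nrow(events) > 0L) {
    events <- events[order(events$patient_id, events$year, events$rule_id,
                           method = "radix"), , drop = FALSE]
    rownames(events) <- NULL
  }
  chronic <- if (length(chron_rows) > 0L) do.call(rbind, chron_rows) else
    data.frame(patient_id = character(0), year = integer(0),
               agents = character(0), acb_total = integer(0),
               stringsAsFactors = FALSE)
  rownames(chronic) <- NULL
  list(events = events, chronic = chronic)
}

#' Write a simulation to disk
#'
#' Emits `claims.csv` and `deaths.csv` in the canonical claims dialect and
#' `ground_truth.json`.
#'
#' @param sim A [generate_claims()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "pim_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("claims.csv", "deaths.csv", "ground_truth.json"))
  write_records(sim$records, paths[1L])
  utils::write.table(
    data.frame(patient_id = sim$deaths$patient_id,
               death_date = format(sim$deaths$death_date, "%Y-%m-%d")),
    paths[2L], sep = ",", row.names = FALSE, quote = TRUE, qmethod = "double")
  jsonlite::write_json(sim$truth, paths[3L], dataframe = "rows",
                       auto_unbox = TRUE)
  invisible(paths)
}

#' @export
print.pim_simulation <- function(x, ...) {
  cat("Synthetic claims simulation (seed ", x$config$seed, ")\n", sep = "")
  cat("  patients: ", x$config$n_patients, "; records: ", nrow(x$records),
      "; deaths: ", nrow(x$deaths), "\n", sep = "")
  cat("  ground-truth events: ", nrow(x$truth$events),
      "; chronic anticholinergic patient-years: ", nrow(x$truth$chronic),
      "\n", sep = "")
  invisible(x)
}
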