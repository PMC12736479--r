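# Rule evaluation against per-patient dispensing histories. All detection
# logic is deterministic: no randomness anywhere in this module.
#
# Date-based conditions operate on distinct dispensing dates: same-day
# duplicate rows of the same drug (pack-level duplication in claims
# exports) collapse to one dispensing event for gap and chronicity
# counting, while raw rows are preserved as event triggers.

#' Gap-based screening for use beyond 8 weeks
#'
#' Screens consecutive dispensing dates of one drug (class) for a pair more
#' than `min_gap_days` apart and within `max_gap_days` — the claims
#' operationalization of "use for more than 8 weeks". Only consecutive
#' pairs are considered; no exposure-episode construction with grace
#' periods is performed.
#'
#' @param dates `Date` vector, ascending, distinct dates of one patient's
#'   dispensations matching one rule.
#' @param min_gap_days Strict lower gap bound in days (default 56).
#' @param max_gap_days Inclusive upper gap bound in days (default 180).
#' @return Logical scalar; attribute `"pairs"` holds a data frame
#'   (`from`, `to`) of every qualifying consecutive pair.
#' @examples
#' duration_over_8_weeks(as.Date(c("2019-01-01", "2019-03-15")))  # gap 73: TRUE
#' @export
duration_over_8_weeks <- function(dates, min_gap_days = 56L,
                                  max_gap_days = 180L) {
  if (length(dates) < 2L) {
    return(structure(FALSE, pairs = data.frame(from = dates[0], to = dates[0])))
  }
  stopifnot(!is.unsorted(dates))
  gaps <- as.integer(diff(dates))
  ok <- gaps > min_gap_days & gaps <= max_gap_days
  structure(any(ok),
            pairs = data.frame(from = dates[-length(dates)][ok],
                               to = dates[-1L][ok]))
}

#' Co-dispensing within a window
#'
#' TRUE when any pair of dates — one from each history of the same patient —
#' lies within `window_days` of each other (default 90 days, the 3-month
#' co-dispensing window).
#'
#' @param dates_a Dates of the index drug (the rule's own ATC match).
#' @param dates_b Dates of the partner drug class.
#' @param window_days Inclusive window in days.
#' @return Logical scalar; attribute `"pairs"` holds the qualifying
#'   (`a`, `b`) date pairs.
#' @export
co_dispensed <- function(dates_a, dates_b, window_days = 90L) {
  if (length(dates_a) == 0L || length(dates_b) == 0L) {
    return(structure(FALSE, pairs = data.frame(a = dates_a[0], b = dates_a[0])))
  }
  d <- abs(outer(as.integer(dates_a), as.integer(dates_b), "-"))
  hit <- which(d <= window_days, arr.ind = TRUE)
  structure(nrow(hit) > 0L,
            pairs = data.frame(a = dates_a[hit[, 1L]], b = dates_b[hit[, 2L]]))
}

#' Chronic use within a calendar year
#'
#' Chronic use of a drug is defined as `min_events` (default 5) or more
#' dispensing events of that drug within one calendar year; events are
#' counted as distinct dispensing dates.
#'
#' @param dates Dispensing dates of one patient for one drug (ATC level 5).
#' @param year Calendar year (integer).
#' @param min_events Chronic-use threshold.
#' @return Logical scalar.
#' @export
chronic_in_year <- function(dates, year, min_events = 5L) {
  length(unique(dates[year_of(dates) == year])) >= min_events
}

#' Unit-dose limit check
#'
#' Compares a dispensation's unit dose (explicit `unit_dose_mg` column,
#' else parsed from the medication name) against a daily-dose threshold.
#' The unit dose is a proxy for the daily dose — prescribed posology is not
#' available in claims. The comparison is strict (`>`).
#'
#' @param record One dispensing record (one-row data frame or list with
#'   `unit_dose_mg` and `medication_name`).
#' @param mg_per_day_threshold Threshold in mg.
#' @return `TRUE`, `FALSE`, or `NA` when no unit dose is available
#'   (indeterminate: the caller skips and logs the rule).
#' @export
unit_dose_exceeds <- function(record, mg_per_day_threshold) {
  dose <- record$unit_dose_mg
  if (is.null(dose) || is.na(dose)) dose <- parse_strength(record$medication_name)
  if (is.na(dose)) return(NA)
  dose > mg_per_day_threshold
}

route_form_dictionary <- function() {
  # priority order matters: parenteral markers beat oral-solution markers
  list(
    list(tokens = c("FL", "FIALA", "FIALE", "VIAL", "VIALS", "INJ", "IV",
                    "IM", "SC"),
         route = "PARENTERAL", form = "SOLUTION"),
    list(tokens = c("CEROTTO", "CEROTTI", "PATCH", "TTS"),
         route = "TRANSDERMAL", form = "PATCH"),
    list(tokens = c("SUPP", "SUPPOSTE", "SUPPOSITORY"),
         route = "RECTAL", form = "SUPPOSITORY"),
    list(tokens = c("COLLIRIO", "EYE"),
         route = "OPHTHALMIC", form = "DROPS"),
    list(tokens = c("CREMA", "CREAM", "UNG", "UNGUENTO", "OINTMENT", "GEL",
                    "POMATA"),
         route = "TOPICAL", form = "CREAM"),
    list(tokens = c("CPR", "TAB", "TABS", "TABLET", "TABLETS", "COMPRESSE"),
         route = "ORAL", form = "TABLET"),
    list(tokens = c("CPS", "CAPS", "CAPSULE", "CAPSULES"),
         route = "ORAL", form = "CAPSULE"),
    list(tokens = c("GTT", "SCIROPPO", "SYRUP", "SOLUZ", "SOLUZIONE", "SOL",
                    "SOLUTION"),
         route = "ORAL", form = "SOLUTION")
  )
}

#' Route and pharmaceutical form from a medication name
#'
#' Administration routes and pharmaceutical forms are not coded in claims;
#' they are derived from the free-text medication name by case-insensitive
#' whole-token keyword matching (multilingual: e.g. `CPR`/`TABS` map to
#' oral tablet, `FL`/`VIAL`/`IV` to parenteral solution, `CREMA`/`CREAM`
#' to topical cream, `SUPP` to rectal, `CEROTTO`/`PATCH` to transdermal).
#' `UNKNOWN`/`UNKNOWN` is returned only when no keyword matches.
#'
#' @param medication_name Character vector of medication names.
#' @return Data frame with columns `route` and `form`, one row per name.
#' @examples
#' parse_route_form("PANTOPRAZOLE 40MG TABS")  # ORAL / TABLET
#' @export
parse_route_form <- function(medication_name) {
  dict <- route_form_dictionary()
  one <- function(name) {
    toks <- strsplit(toupper(name), "[^A-Z0-9%]+")[[1]]
    for (entry in dict) {
      if (any(toks %in% entry$tokens)) {
        return(c(entry$route, entry$form))
      }
    }
    c("UNKNOWN", "UNKNOWN")
  }
  m <- vapply(medication_name, one, character(2))
  data.frame(route = m[1L, ], form = m[2L, ], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Unit strength (mg) from a medication name
#'
#' Returns the first number immediately followed by an `mg` or `g` token
#' (grams converted to mg); `NA` when no such token exists (e.g. IU-dosed
#' products).
#'
#' @param medication_name Character vector.
#' @return Numeric vector of mg values (`NA` where absent).
#' @examples
#' parse_strength("ASA 500MG TABS")   # 500
#' parse_strength("METFORMIN 1G")     # 1000
#' @export
parse_strength <- function(medication_name) {
  up <- toupper(medication_name)
  m <- regexpr("([0-9]+(?:[.,][0-9]+)?) ?(MG|G)\\b", up, perl = TRUE)
  vapply(seq_along(up), function(i) {
    if (m[i] == -1L) return(NA_real_)
    tok <- substr(up[i], m[i], m[i] + attr(m, "match.length")[i] - 1L)
    num <- as.numeric(sub(",", ".", sub(" ?(MG|G)$", "", tok)))
    if (grepl("MG$", tok)) num else num * 1000
  }, numeric(1))
}

# Recursive condition evaluation for one patient, rule and year.
# Returns TRUE / FALSE / NA (NA: indeterminate, e.g. missing unit dose).
eval_condition <- function(cond, history, matched, year) {
  in_year <- year_of(history$dispense_date) == year
  switch(cond$type,
    ALWAYS = any(matched & in_year),
    DURATION_OVER_8_WEEKS = {
      dates <- sort(unique(history$dispense_date[matched]))
      res <- duration_over_8_weeks(dates,
                                   cond$min_gap_days %||% 56L,
                                   cond$max_gap_days %||% 180L)
      pairs <- attr(res, "pairs")
      isTRUE(res) && any(year_of(pairs$to) == year)
    },
    CO_DISPENSED_WITH = {
      a <- sort(unique(history$dispense_date[matched]))
      bmatch <- atc_matches_prefix(history$atc_code,
                                   toupper(unlist(cond$atc)))
      b <- sort(unique(history$dispense_date[bmatch]))
      res <- co_dispensed(a, b, cond$window_days %||% 90L)
      pairs <- attr(res, "pairs")
      isTRUE(res) && any(year_of(pairs$a) == year)
    },
    UNIT_DOSE_EXCEEDS = {
      idx <- which(matched & in_year)
      if (length(idx) == 0L) return(FALSE)
      verdicts <- vapply(idx, function(i) {
        unit_dose_exceeds(history[i, , drop = FALSE], cond$mg_per_day)
      }, NA)
      if (any(verdicts %in% TRUE)) TRUE
      else if (all(is.na(verdicts))) NA
      else FALSE
    },
    ROUTE_IS = {
      idx <- which(matched & in_year)
      length(idx) > 0L &&
        any(parse_route_form(history$medication_name[idx])$route == cond$route)
    },
    FORM_IS = {
      idx <- which(matched & in_year)
      length(idx) > 0L &&
        any(parse_route_form(history$medication_name[idx])$form == cond$form)
    },
    CHRONIC_USE = {
      codes <- unique(history$atc_code[matched])
      any(vapply(codes, function(code) {
        chronic_in_year(history$dispense_date[history$atc_code == code],
                        year, cond$min_events %||% 5L)
      }, NA))
    },
    ALL_OF = {
      verdicts <- vapply(cond$conditions, eval_condition, NA,
                         history = history, matched = matched, year = year)
      if (any(verdicts %in% FALSE)) FALSE
      else if (anyNA(verdicts)) NA
      else TRUE
    },
    stop("unknown condition type: ", cond$type)
  )
}

#' Evaluate one rule for one patient and year
#'
#' Emits a PIM event iff some dispensation in `year` matches the rule's ATC
#' patterns and the rule's applicability condition holds. Year attribution:
#' a duration event belongs to the year of the later date of a qualifying
#' gap pair; a co-dispensing event to the year of the index-drug date;
#' other conditions to the year of the matching dispensation.
#'
#' @param history Dispensing records of a single patient.
#' @param rule One catalog rule (an element of `catalog$rules`).
#' @param year Calendar year to attribute events to.
#' @param catalog The containing `"beers_catalog"` (for context; conditions
#'   are self-contained).
#' @return `NULL` (no event), or a list with `patient_id`, `rule_id`,
#'   `category`, `label`, `year` and `triggers` (row indices into
#'   `history`, or its `.row` column when present). An indeterminate
#'   unit-dose evaluation returns an empty object of class
#'   `"pim_rule_skip"` so callers can log it.
#' @export
evaluate_rule <- function(history, rule, year, catalog = NULL) {
  stopifnot(length(unique(history$patient_id)) <= 1L)
  matched <- atc_matches_prefix(history$atc_code, rule$atc)
  if (!any(matched)) return(NULL)
  verdict <- eval_condition(rule$condition, history, matched, year)
  in_year <- matched & year_of(history$dispense_date) == year
  if (is.na(verdict)) {
    return(structure(list(), class = "pim_rule_skip"))
  }
  if (!verdict || !any(in_year)) return(NULL)
  rows <- if (".row" %in% names(history)) history$.row[in_year] else which(in_year)
  list(patient_id = history$patient_id[1L], rule_id = rule$id,
       category = rule$category, label = rule$label, year = year,
       triggers = rows,
       first_trigger_date = min(history$dispense_date[in_year]))
}

empty_events <- function() {
  data.frame(patient_id = character(0), year = integer(0),
             rule_id = character(0), category = character(0),
             label = character(0), n_triggers = integer(0),
             first_trigger_date = as.Date(character(0)),
             stringsAsFactors = FALSE)
}

#' Detect all PIM events in a cohort
#'
#' Runs every catalog rule against every eligible patient's full dispensing
#' history for every window year, emitting at most one event per
#' (patient, rule, year). The result is exactly the union of
#' [evaluate_rule()] outcomes, ordered by patient id, year, rule id.
#'
#' @param cohort A [build_cohort()] result.
#' @param records Dispensing records (the same table the cohort was built
#'   from; records outside the window still provide gap context).
#' @param catalog A `"beers_catalog"`.
#' @return Data frame with columns `patient_id`, `year`, `rule_id`,
#'   `category`, `label`, `n_triggers`, `first_trigger_date`, and a
#'   list-column `triggers` of row indices into `records`. Rules skipped
#'   for indeterminate unit dose are collected in the `"skipped"`
#'   attribute.
#' @export
detect_all <- function(cohort, records, catalog = default_catalog()) {
  stopifnot(inherits(cohort, "pim_cohort"), inherits(catalog, "beers_catalog"))
  years <- cohort$window$years
  rules <- catalog$rules

  keep <- records$patient_id %in% cohort$patients$patient_id
  rec <- records[keep, , drop = FALSE]
  rec$.row <- which(keep)
  if (nrow(rec) == 0L || length(rules) == 0L) {
    ev <- empty_events()
    ev$triggers <- list()
    attr(ev, "skipped") <- data.frame(patient_id = character(0),
                                      rule_id = character(0),
                                      year = integer(0))
    return(ev)
  }

  # map each observed ATC code to the rules it can trigger
  ucodes <- unique(rec$atc_code)
  rule_hits <- lapply(rules, function(r) ucodes[atc_matches_prefix(ucodes, r$atc)])
  code_rules <- stats::setNames(rep(list(character(0)), length(ucodes)), ucodes)
  for (rid in names(rule_hits)) {
    for (code in rule_hits[[rid]]) code_rules[[code]] <- c(code_rules[[code]], rid)
  }

  by_patient <- split(seq_len(nrow(rec)), rec$patient_id)
  events <- vector("list", 1000L); n_ev <- 0L
  skips <- list()
  for (pid in names(by_patient)) {
    hist <- rec[by_patient[[pid]], , drop = FALSE]
    cand <- unique(unlist(code_rules[unique(hist$atc_code)]))
    if (length(cand) == 0L) next
    hist_years <- unique(year_of(hist$dispense_date))
    for (rid in sort(cand, method = "radix")) {
      rule <- rules[[rid]]
      matched_years <- intersect(
        unique(year_of(hist$dispense_date[
          atc_matches_prefix(hist$atc_code, rule$atc)])), years)
      for (y in matched_years) {
        ev <- evaluate_rule(hist, rule, y, catalog)
        if (inherits(ev, "pim_rule_skip")) {
          skips[[length(skips) + 1L]] <-
            data.frame(patient_id = pid, rule_id = rid, year = y)
          next
        }
        if (is.null(ev)) next
        n_ev <- n_ev + 1L
        if (n_ev > length(events)) events <- c(events, vector("list", n_ev))
        events[[n_ev]] <- ev
      }
    }
  }
  events <- events[seq_len(n_ev)]
  if (n_ev == 0L) {
    out <- empty_events()
    out$triggers <- list()
  } else {
    out <- data.frame(
      patient_id = vapply(events, `[[`, "", "patient_id"),
      year = vapply(events, `[[`, 0L, "year"),
      rule_id = vapply(events, `[[`, "", "rule_id"),
      category = vapply(events, `[[`, "", "category"),
      label = vapply(events, `[[`, "", "label"),
      n_triggers = vapply(events, function(e) length(e$triggers), 0L),
      first_trigger_date = as.Date(
        vapply(events, function(e) as.character(e$first_trigger_date), "")),
      stringsAsFactors = FALSE
    )
    out$triggers <- lapply(events, `[[`, "triggers")
    ord <- order(out$patient_id, out$year, out$rule_id, method = "radix")
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- if (length(skips) > 0L) {
    do.call(rbind, skips)
  } else {
    data.frame(patient_id = character(0), rule_id = character(0),
               year = integer(0))
  }
  out
}

#' Export detected events as CSV
#'
#' @param events A [detect_all()] result.
#' @param path Output path.
#' @return Invisibly, the number of rows written.
#' @export
export_events <- function(events, path) {
  out <- events[, c("patient_id", "year", "rule_id", "category", "label",
                    "n_triggers", "first_trigger_date")]
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = TRUE,
                     qmethod = "double", fileEncoding = "UTF-8")
  invisible(nrow(out))
}
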