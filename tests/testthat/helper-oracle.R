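# Independent brute-force PIM evaluator: explicit loops and exhaustive
# pair enumeration, written without reusing the package's condition
# predicates, used as the oracle for detect_all().

bf_match <- function(code, prefixes) {
  for (p in prefixes) {
    if (substr(code, 1L, nchar(p)) == p) return(TRUE)
  }
  FALSE
}

bf_year <- function(d) as.integer(format(d, "%Y"))

bf_condition <- function(cond, hist, matched, year) {
  in_year <- bf_year(hist$dispense_date) == year
  if (cond$type == "ALWAYS") {
    return(any(matched & in_year))
  }
  if (cond$type == "DURATION_OVER_8_WEEKS") {
    lo <- if (is.null(cond$min_gap_days)) 56L else cond$min_gap_days
    hi <- if (is.null(cond$max_gap_days)) 180L else cond$max_gap_days
    d <- sort(unique(hist$dispense_date[matched]))
    if (length(d) < 2L) return(FALSE)
    for (i in seq_len(length(d) - 1L)) {
      gap <- as.integer(d[i + 1L] - d[i])
      if (gap > lo && gap <= hi && bf_year(d[i + 1L]) == year) return(TRUE)
    }
    return(FALSE)
  }
  if (cond$type == "CO_DISPENSED_WITH") {
    w <- if (is.null(cond$window_days)) 90L else cond$window_days
    a <- unique(hist$dispense_date[matched])
    bm <- vapply(hist$atc_code, bf_match, NA,
                 prefixes = toupper(unlist(cond$atc)))
    b <- unique(hist$dispense_date[bm])
    for (da in a) {
      for (db in b) {
        if (abs(da - db) <= w && bf_year(as.Date(da, origin = "1970-01-01"))
            == year) {
          return(TRUE)
        }
      }
    }
    return(FALSE)
  }
  if (cond$type == "UNIT_DOSE_EXCEEDS") {
    idx <- which(matched & in_year)
    if (length(idx) == 0L) return(FALSE)
    verdicts <- logical(0)
    for (i in idx) {
      dose <- hist$unit_dose_mg[i]
      if (!is.na(dose)) verdicts <- c(verdicts, dose > cond$mg_per_day)
    }
    if (length(verdicts) == 0L) return(NA)
    return(any(verdicts))
  }
  if (cond$type == "CHRONIC_USE") {
    k <- if (is.null(cond$min_events)) 5L else cond$min_events
    for (code in unique(hist$atc_code[matched])) {
      d <- hist$dispense_date[hist$atc_code == code]
      if (length(unique(d[bf_year(d) == year])) >= k) return(TRUE)
    }
    return(FALSE)
  }
  if (cond$type == "ALL_OF") {
    verdicts <- vapply(cond$conditions, bf_condition, NA, hist = hist,
                       matched = matched, year = year)
    if (any(verdicts %in% FALSE)) return(FALSE)
    if (anyNA(verdicts)) return(NA)
    return(TRUE)
  }
  stop("oracle: unhandled condition type ", cond$type)
}

brute_force_detect <- function(cohort, records, catalog) {
  out <- list()
  for (pid in cohort$patients$patient_id) {
    hist <- records[records$patient_id == pid, , drop = FALSE]
    for (rid in names(catalog$rules)) {
      rule <- catalog$rules[[rid]]
      matched <- vapply(hist$atc_code, bf_match, NA, prefixes = rule$atc)
      if (!any(matched)) next
      for (year in cohort$window$years) {
        has_in_year <- any(matched & bf_year(hist$dispense_date) == year)
        verdict <- bf_condition(rule$condition, hist, matched, year)
        if (isTRUE(verdict) && has_in_year) {
          out[[length(out) + 1L]] <- data.frame(
            patient_id = pid, year = year, rule_id = rid,
            category = rule$category, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(patient_id = character(0), year = integer(0),
                      rule_id = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$patient_id, res$year, res$rule_id, method = "radix"), ]
  rownames(res) <- NULL
  res
}

# random micro-cohort over a handful of catalog drugs, explicit unit doses
# so dose rules are decidable without name parsing
random_micro_cohort <- function(seed) {
  set.seed(seed)
  pool <- list(
    c("A02BC02", "PANTOPRAZOLE 40MG TABS", "40"),
    c("N06AB05", "PAROXETINE 20MG TABS", "20"),
    c("C03CA01", "FUROSEMIDE 25MG TABS", "25"),
    c("B01AC05", "TICLOPIDINE 250MG TABS", "250"),
    c("M01AB05", "DICLOFENAC 50MG TABS", "50"),
    c("B01AA03", "WARFARIN 5MG TABS", "5"),
    c("B01AC06", "ASPIRIN TABS", NA),     # dose drawn per record
    c("N06AA09", "AMITRIPTYLINE 25MG TABS", "25"),
    c("N02BE01", "PARACETAMOL 500MG TABS", "500")
  )
  drugs <- pool[sort(sample.int(length(pool), sample(2:5, 1L)))]
  n_pat <- sample(3:10, 1L)
  rows <- list()
  for (i in seq_len(n_pat)) {
    pid <- sprintf("M%03d", i)
    birth <- as.character(as.Date("1935-01-01") + sample.int(7000L, 1L))
    for (d in drugs) {
      k <- sample(0:7, 1L)
      if (k == 0L) next
      dates <- as.Date("2018-01-01") + sample.int(1461L, k)
      dose <- if (is.na(d[3])) sample(c(100, 325, 500, NA), k, replace = TRUE)
              else as.numeric(d[3])
      rows[[length(rows) + 1L]] <- make_records(
        pid, dates, d[1], medication_name = d[2],
        birth_date = birth, unit_dose_mg = dose)
    }
  }
  if (length(rows) == 0L) return(random_micro_cohort(seed + 10000L))
  do.call(rbind, rows)
}
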