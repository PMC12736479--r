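# Study eligibility, exclusions, and age/sex stratification.

#' Study window
#'
#' @param start,end Window bounds (`Date` or ISO strings). Defaults
#'   2018-01-01 to 2021-12-31, a four-calendar-year observation period.
#' @return A `"study_window"` object with `start`, `end` and the covered
#'   calendar `years`.
#' @export
study_window <- function(start = "2018-01-01", end = "2021-12-31") {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(!is.na(start), !is.na(end), start < end)
  structure(list(start = start, end = end,
                 years = seq.int(year_of(start), year_of(end))),
            class = "study_window")
}

#' Completed age in years at a reference date
#'
#' Birthday-anniversary arithmetic: the age increments on the anniversary
#' of the birth date (29 February birthdays increment on 1 March in common
#' years).
#'
#' @param birth_date,reference_date `Date` vectors (recycled).
#' @return Integer vector of completed years.
#' @examples
#' age_at(as.Date("1950-06-15"), as.Date("2021-12-31"))  # 71
#' @export
age_at <- function(birth_date, reference_date) {
  stopifnot(all(reference_date >= birth_date))
  by <- year_of(birth_date); ry <- year_of(reference_date)
  bmd <- as.integer(format(birth_date, "%m%d"))
  rmd <- as.integer(format(reference_date, "%m%d"))
  as.integer(ry - by - (rmd < bmd))
}

#' Age stratum of an older adult
#'
#' Strata: young elderly (65-74), elderly (75-84), very elderly (85+).
#'
#' @param age Integer vector of ages, all >= 65.
#' @return Factor with levels `YOUNG_ELDERLY`, `ELDERLY`, `VERY_ELDERLY`.
#' @export
age_group <- function(age) {
  if (any(age < 65)) stop("age_group() is defined for ages >= 65")
  cut(age, breaks = c(65, 75, 85, Inf), right = FALSE,
      labels = c("YOUNG_ELDERLY", "ELDERLY", "VERY_ELDERLY"))
}

#' Build the eligible study cohort
#'
#' A patient enters the cohort iff they reach age 65 on or before the window
#' end (so those turning 65 during the study period are included), have at
#' least one dispensation inside the window, and have no registered death on
#' or before the window end. Age and age stratum are computed once, at the
#' window end. Yearly denominators collect, per calendar year, the eligible
#' patients with at least one dispensation that year.
#'
#' @param records Dispensing records (see [read_dispensing()]).
#' @param deaths Optional death-registry data frame (`patient_id`,
#'   `death_date`); `NULL` means no exclusions for death.
#' @param window A [study_window()].
#' @return A `"pim_cohort"` object: `window`; `patients` (data frame with
#'   `patient_id`, `birth_date`, `sex`, `death_date`, `age`, `age_group`);
#'   `yearly_denominators` (named list, year to character vector of patient
#'   ids).
#' @export
build_cohort <- function(records, deaths = NULL, window = study_window()) {
  stopifnot(inherits(window, "study_window"))
  if (nrow(records) == 0L) {
    patients <- data.frame(patient_id = character(0),
                           birth_date = as.Date(character(0)),
                           sex = character(0),
                           death_date = as.Date(character(0)),
                           age = integer(0),
                           age_group = factor(character(0),
                             levels = c("YOUNG_ELDERLY", "ELDERLY",
                                        "VERY_ELDERLY")))
    denom <- stats::setNames(
      rep(list(character(0)), length(window$years)), window$years)
    return(structure(list(window = window, patients = patients,
                          yearly_denominators = denom),
                     class = "pim_cohort"))
  }

  first <- !duplicated(records$patient_id)
  patients <- data.frame(patient_id = records$patient_id[first],
                         birth_date = records$birth_date[first],
                         sex = records$sex[first],
                         stringsAsFactors = FALSE)
  # one birth date per patient is a hard data-quality requirement
  chk <- tapply(as.integer(records$birth_date), records$patient_id,
                function(v) length(unique(v)))
  if (any(chk > 1L)) {
    stop("inconsistent birth_date for patient_id(s): ",
         paste(utils::head(names(chk)[chk > 1L], 5L), collapse = ", "))
  }

  if (!is.null(deaths) && nrow(deaths) > 0L) {
    patients$death_date <- deaths$death_date[
      match(patients$patient_id, deaths$patient_id)]
  } else {
    patients$death_date <- as.Date(rep(NA, nrow(patients)))
  }

  in_window <- records$dispense_date >= window$start &
    records$dispense_date <= window$end
  has_disp <- patients$patient_id %in% records$patient_id[in_window]
  old_enough <- age_at(patients$birth_date,
                       rep(window$end, nrow(patients))) >= 65L
  alive <- is.na(patients$death_date) | patients$death_date > window$end
  keep <- has_disp & old_enough & alive
  patients <- patients[keep, , drop = FALSE]
  rownames(patients) <- NULL
  patients$age <- age_at(patients$birth_date,
                         rep(window$end, nrow(patients)))
  patients$age_group <- age_group(patients$age)

  rec <- records[in_window & records$patient_id %in% patients$patient_id, ,
                 drop = FALSE]
  yr <- year_of(rec$dispense_date)
  denom <- lapply(window$years, function(y) {
    sort(unique(rec$patient_id[yr == y]))
  })
  names(denom) <- window$years

  structure(list(window = window, patients = patients,
                 yearly_denominators = denom),
            class = "pim_cohort")
}

#' @export
print.pim_cohort <- function(x, ...) {
  cat("PIM study cohort: ", nrow(x$patients), " eligible patients, ",
      format(x$window$start), " to ", format(x$window$end), "\n", sep = "")
  if (nrow(x$patients) > 0L) {
    cat("  male: ", sum(x$patients$sex == "M"), "; strata: ",
        paste(sprintf("%s %d", levels(x$patients$age_group),
                      as.integer(table(x$patients$age_group))),
              collapse = ", "), "\n", sep = "")
  }
  cat("  yearly denominators:",
      paste(sprintf("%s=%d", names(x$yearly_denominators),
                    lengths(x$yearly_denominators)), collapse = ", "), "\n")
  invisible(x)
}
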