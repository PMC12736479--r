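# Annual prevalence, ranked PIM frequency tables, and descriptive
# statistics of the screened sample.

#' Printed percentage with half-up rounding
#'
#' All reported percentages use half-up rounding at one decimal (R's
#' [round()] rounds half to even, which does not reproduce printed
#' drug-utilization tables).
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @param decimals Decimal places (default 1).
#' @return Numeric percentage.
#' @examples
#' percent(65807, 115962)  # 56.7
#' @export
percent <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("numerator must lie in [0, denominator]")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Annual PIM prevalence
#'
#' Per calendar year: the number of distinct patients with at least one
#' (optionally category-filtered) PIM event, over the number of older
#' adults with at least one dispensation that year; plus a `"total"` cell
#' over the whole window (distinct patients with any event / distinct
#' patients with any dispensation in the window).
#'
#' @param events A [detect_all()] result.
#' @param cohort The matching [build_cohort()] result.
#' @param category Optional filter: `"AVOID"`, `"CAUTION"` or
#'   `"ANTICHOLINERGIC"`.
#' @return Data frame of cells: `stratum`, `period`, `numerator`,
#'   `denominator`, `percent`.
#' @export
annual_prevalence <- function(events, cohort, category = NULL) {
  stopifnot(inherits(cohort, "pim_cohort"))
  ev <- events
  if (!is.null(category)) {
    stopifnot(category %in% PIM_CATEGORIES)
    ev <- ev[ev$category == category, , drop = FALSE]
  }
  stratum <- if (is.null(category)) "all" else category
  cells <- lapply(cohort$window$years, function(y) {
    denom_ids <- cohort$yearly_denominators[[as.character(y)]]
    if (is.null(denom_ids)) stop("no denominator for year ", y)
    num <- length(unique(ev$patient_id[ev$year == y]))
    data.frame(stratum = stratum, period = as.character(y),
               numerator = num, denominator = length(denom_ids),
               percent = if (length(denom_ids) > 0L)
                 percent(num, length(denom_ids)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  total_denom <- length(unique(unlist(cohort$yearly_denominators)))
  total_num <- length(unique(ev$patient_id))
  cells[[length(cells) + 1L]] <- data.frame(
    stratum = stratum, period = "total",
    numerator = total_num, denominator = total_denom,
    percent = if (total_denom > 0L) percent(total_num, total_denom)
              else NA_real_,
    stringsAsFactors = FALSE)
  do.call(rbind, cells)
}

#' Ranked PIM frequency table for a year
#'
#' Groups events of one category and year by reporting label (class rules
#' are already grouped at ATC level 4 through catalog labels), counts
#' distinct patients per group, and ranks groups by descending patient
#' count (ties broken by label, ascending). The denominator is the number
#' of distinct patients with any event of that category that year. An
#' optional inclusion threshold (e.g. groups dispensed to more than 2% of
#' those patients) is applied before the top-`k` cut.
#'
#' @param events A [detect_all()] result.
#' @param year Calendar year.
#' @param category PIM category.
#' @param top_k Number of ranks to keep (default 6).
#' @param min_percent Optional minimum percentage for inclusion.
#' @return Data frame: `year`, `category`, `rank`, `label`, `n_patients`,
#'   `percent`.
#' @export
rank_pims <- function(events, year, category, top_k = 6L,
                      min_percent = NULL) {
  stopifnot(category %in% PIM_CATEGORIES)
  ev <- events[events$year == year & events$category == category, ,
               drop = FALSE]
  out <- data.frame(year = integer(0), category = character(0),
                    rank = integer(0), label = character(0),
                    n_patients = integer(0), percent = numeric(0),
                    stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) return(out)
  denom <- length(unique(ev$patient_id))
  counts <- tapply(ev$patient_id, ev$label,
                   function(v) length(unique(v)))
  labels <- names(counts)
  n <- as.integer(counts)
  ord <- order(-n, labels, method = "radix")
  labels <- labels[ord]; n <- n[ord]
  pct <- percent(n, denom)
  keep <- seq_along(labels) <= top_k
  if (!is.null(min_percent)) keep <- keep & pct > min_percent
  data.frame(year = year, category = category,
             rank = seq_along(labels)[keep], label = labels[keep],
             n_patients = n[keep], percent = pct[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ATC level-4 group of a level-5 code
#'
#' The chemical/pharmacological subgroup: the first 5 characters. Codes
#' shorter than a full level-5 code are returned unchanged, with a
#' warning.
#'
#' @param atc_code Character vector of ATC codes.
#' @return Character vector of level-4 prefixes.
#' @export
group_atc_level4 <- function(atc_code) {
  short <- nchar(atc_code) < 7L
  if (any(short)) {
    warning("code(s) shorter than ATC level 5 returned unchanged: ",
            paste(atc_code[short], collapse = ", "))
  }
  ifelse(short, atc_code, substr(atc_code, 1L, 5L))
}

median_iqr <- function(x) {
  # quartiles by linear interpolation between order statistics
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(q1 = q[1L], median = q[2L], q3 = q[3L])
}

#' Descriptive summary of patients with PIMs
#'
#' Per calendar year and over the whole window: number of distinct
#' patients with at least one PIM event, number and percentage male,
#' median [IQR] age (computed at the window end), median [IQR] PIM
#' dispensations per patient (trigger dispensations, the convention that
#' reproduces claims-level medians), and number and percentage of patients
#' per PIM category.
#'
#' @param cohort A [build_cohort()] result.
#' @param events The matching [detect_all()] result.
#' @return Data frame, one row per period (`"2018"`, ..., `"total"`).
#' @export
summarize_sample <- function(cohort, events) {
  stopifnot(inherits(cohort, "pim_cohort"))
  periods <- c(as.character(cohort$window$years), "total")
  pat <- cohort$patients
  rows <- lapply(periods, function(p) {
    ev <- if (p == "total") events else events[events$year == as.integer(p), ,
                                               drop = FALSE]
    ids <- unique(ev$patient_id)
    n <- length(ids)
    if (n == 0L) {
      return(data.frame(period = p, n_patients = 0L, n_male = 0L,
                        pct_male = NA_real_, age_median = NA_real_,
                        age_q1 = NA_real_, age_q3 = NA_real_,
                        pims_median = NA_real_, pims_q1 = NA_real_,
                        pims_q3 = NA_real_, n_avoid = 0L, pct_avoid = NA_real_,
                        n_caution = 0L, pct_caution = NA_real_,
                        n_anticholinergic = 0L,
                        pct_anticholinergic = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sel <- pat[match(ids, pat$patient_id), , drop = FALSE]
    n_male <- sum(sel$sex == "M", na.rm = TRUE)
    a <- median_iqr(sel$age)
    per_patient <- tapply(ev$n_triggers, ev$patient_id, sum)
    k <- median_iqr(as.numeric(per_patient))
    cat_n <- vapply(PIM_CATEGORIES, function(cc) {
      length(unique(ev$patient_id[ev$category == cc]))
    }, 0L)
    data.frame(period = p, n_patients = n, n_male = n_male,
               pct_male = percent(n_male, n),
               age_median = a[["median"]], age_q1 = a[["q1"]],
               age_q3 = a[["q3"]],
               pims_median = k[["median"]], pims_q1 = k[["q1"]],
               pims_q3 = k[["q3"]],
               n_avoid = cat_n[["AVOID"]],
               pct_avoid = percent(cat_n[["AVOID"]], n),
               n_caution = cat_n[["CAUTION"]],
               pct_caution = percent(cat_n[["CAUTION"]], n),
               n_anticholinergic = cat_n[["ANTICHOLINERGIC"]],
               pct_anticholinergic = percent(cat_n[["ANTICHOLINERGIC"]], n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
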