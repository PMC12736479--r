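# One-call screening pipeline: cohort -> detection -> reporting, returned
# as a single classed object.

#' Screen dispensing claims for potentially inappropriate medications
#'
#' Runs the full pipeline: builds the eligible older-adult cohort, detects
#' PIM events with the rule catalog, and derives annual prevalences
#' (overall and per category).
#'
#' @param records Dispensing records (see [read_dispensing()]).
#' @param deaths Optional death-registry data frame.
#' @param catalog A `"beers_catalog"` (default: the shipped 2019 catalog).
#' @param window A [study_window()].
#' @return A `"pim_screen"` object with elements `cohort`, `events`,
#'   `prevalence` (overall and per-category annual cells), `catalog` and
#'   `window`.
#' @examples
#' \dontrun{
#' sim <- generate_claims(sim_config(n_patients = 500, seed = 7))
#' scr <- pim_screen(sim$records, sim$deaths)
#' summary(scr)
#' }
#' @export
pim_screen <- function(records, deaths = NULL, catalog = default_catalog(),
                       window = study_window()) {
  cohort <- build_cohort(records, deaths, window)
  events <- detect_all(cohort, records, catalog)
  prevalence <- do.call(rbind, c(
    list(annual_prevalence(events, cohort)),
    lapply(PIM_CATEGORIES, function(cc) annual_prevalence(events, cohort, cc))
  ))
  structure(list(cohort = cohort, events = events, prevalence = prevalence,
                 catalog = catalog, window = window),
            class = "pim_screen")
}

#' @export
print.pim_screen <- function(x, ...) {
  tot <- x$prevalence[x$prevalence$stratum == "all" &
                        x$prevalence$period == "total", ]
  cat("PIM screening, ", format(x$window$start), " to ",
      format(x$window$end), "\n", sep = "")
  cat("  eligible patients: ", nrow(x$cohort$patients), "\n", sep = "")
  cat("  PIM events: ", nrow(x$events), "; patients with >=1 PIM: ",
      tot$numerator, "/", tot$denominator,
      if (!is.na(tot$percent)) sprintf(" (%.1f%%)", tot$percent) else "",
      "\n", sep = "")
  invisible(x)
}

#' Summary of a screening run
#'
#' @param object A `"pim_screen"` object.
#' @param top_k Ranks to show per category in the final window year.
#' @param ... Unused.
#' @return A `"summary.pim_screen"` list: `prevalence`, `sample` (the
#'   descriptive table from [summarize_sample()]) and `ranks` (top PIM
#'   groups per category, final year).
#' @export
summary.pim_screen <- function(object, top_k = 6L, ...) {
  last_year <- max(object$window$years)
  ranks <- do.call(rbind, lapply(PIM_CATEGORIES, function(cc) {
    rank_pims(object$events, last_year, cc, top_k = top_k)
  }))
  structure(list(prevalence = object$prevalence,
                 sample = summarize_sample(object$cohort, object$events),
                 ranks = ranks, window = object$window),
            class = "summary.pim_screen")
}

#' @export
print.summary.pim_screen <- function(x, ...) {
  cat("Annual prevalence of patients with PIMs (% of patients with",
      "dispensations):\n")
  wide <- stats::reshape(
    x$prevalence[, c("stratum", "period", "percent")],
    idvar = "stratum", timevar = "period", direction = "wide")
  names(wide) <- sub("^percent\\.", "", names(wide))
  print(wide, row.names = FALSE)
  cat("\nTop PIM groups, ", max(x$window$years), " (% of patients with ",
      "PIMs of that category):\n", sep = "")
  print(x$ranks, row.names = FALSE)
  invisible(x)
}

#' Plot annual PIM prevalence
#'
#' Line plot of annual prevalence (overall and per category) across the
#' study window.
#'
#' @param x A `"pim_screen"` object.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of plotted percentages.
#' @export
plot.pim_screen <- function(x, ...) {
  p <- x$prevalence[x$prevalence$period != "total", ]
  strata <- unique(p$stratum)
  years <- sort(unique(as.integer(p$period)))
  m <- sapply(strata, function(s) {
    p$percent[p$stratum == s][order(as.integer(p$period[p$stratum == s]))]
  })
  graphics::matplot(years, m, type = "b", pch = 19, lty = 1,
                    xlab = "Year", ylab = "Patients with PIMs (%)",
                    ylim = c(0, max(m, na.rm = TRUE) * 1.15), xaxt = "n", ...)
  graphics::axis(1, at = years)
  graphics::legend("topleft", legend = strata, col = seq_along(strata),
                   pch = 19, lty = 1, bty = "n", cex = 0.85)
  invisible(m)
}

#' Write the standard report tables
#'
#' Emits `prevalence.csv`, `ranks.csv`, `sample_summary.csv`,
#' `chronic_anticholinergics.csv` and a `manifest.json` run manifest
#' (catalog version and row counts).
#'
#' @param x A `"pim_screen"` object.
#' @param records The dispensing records the object was built from (needed
#'   for chronic-user histories).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, records, dir) {
  stopifnot(inherits(x, "pim_screen"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- summary(x)
  last_year <- max(x$window$years)
  eligible <- records$patient_id %in% x$cohort$patients$patient_id
  chronic <- summarize_chronic_users(records[eligible, , drop = FALSE],
                                     last_year, x$catalog)
  paths <- file.path(dir, c("prevalence.csv", "ranks.csv",
                            "sample_summary.csv",
                            "chronic_anticholinergics.csv",
                            "manifest.json"))
  utils::write.csv(x$prevalence, paths[1L], row.names = FALSE)
  utils::write.csv(s$ranks, paths[2L], row.names = FALSE)
  utils::write.csv(s$sample, paths[3L], row.names = FALSE)
  utils::write.csv(chronic$users, paths[4L], row.names = FALSE)
  jsonlite::write_json(
    list(catalog_version = x$catalog$version,
         window = c(format(x$window$start), format(x$window$end)),
         n_patients = nrow(x$cohort$patients),
         n_events = nrow(x$events),
         n_chronic_users = nrow(chronic$users)),
    paths[5L], auto_unbox = TRUE)
  invisible(paths)
}
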