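# Chronic users of strong anticholinergics and anticholinergic cognitive
# burden (ACB) totals per patient-year.

#' Chronic strong-anticholinergic agents of one patient in a year
#'
#' An agent (distinct ATC level-5 code) qualifies when it matches an
#' ANTICHOLINERGIC catalog rule and is used chronically that year
#' (>= `min_events` distinct dispensing dates).
#'
#' @param history Dispensing records of one patient.
#' @param year Calendar year.
#' @param catalog A `"beers_catalog"`.
#' @param min_events Chronic-use threshold (default 5 dispensations/year).
#' @return Character vector of qualifying ATC level-5 codes (sorted).
#' @export
chronic_anticholinergics <- function(history, year,
                                     catalog = default_catalog(),
                                     min_events = 5L) {
  stopifnot(length(unique(history$patient_id)) <= 1L)
  achol <- catalog$rules[vapply(catalog$rules, `[[`, "", "category") ==
                           "ANTICHOLINERGIC"]
  patterns <- unique(toupper(unlist(lapply(achol, `[[`, "atc"))))
  codes <- unique(history$atc_code[atc_matches_prefix(history$atc_code,
                                                      patterns)])
  keep <- vapply(codes, function(code) {
    chronic_in_year(history$dispense_date[history$atc_code == code],
                    year, min_events)
  }, NA)
  sort(codes[keep])
}

#' Total ACB score of a set of agents
#'
#' Additive, permutation-invariant sum of per-agent ACB scores
#' (longest-prefix lookup in the catalog's ACB table). An agent absent from
#' the table contributes 0, with a warning.
#'
#' @param agents Character vector of ATC level-5 codes.
#' @param catalog A `"beers_catalog"`.
#' @return Integer total burden score.
#' @examples
#' \dontrun{
#' acb_total(c("N06AB05", "N06AA09", "G04BD04"))  # 3 agents x score 3 = 9
#' }
#' @export
acb_total <- function(agents, catalog = default_catalog()) {
  if (length(agents) == 0L) return(0L)
  scores <- vapply(agents, acb_score_of, 0L, catalog = catalog)
  if (any(scores == 0L)) {
    warning("agent(s) not in the ACB table contribute 0: ",
            paste(agents[scores == 0L], collapse = ", "))
  }
  sum(scores)
}

#' Summarize chronic anticholinergic users
#'
#' Builds the per-patient chronic-user table for one year (agents and ACB
#' total) plus patient-level frequencies by therapeutic class. Class
#' grouping is a configurable ATC-prefix map; by default antidepressants
#' (N06A), antipsychotics (N05A) and urinary antispasmodics (G04BD), with
#' any remaining agent reported under its own rule label. A patient
#' chronically using two drugs of one class is counted once in that class;
#' percentages are relative to the total number of chronic users.
#'
#' @param records Dispensing records (all patients).
#' @param year Calendar year.
#' @param catalog A `"beers_catalog"`.
#' @param class_map Named character vector, class label -> ATC prefix.
#' @param min_events Chronic-use threshold.
#' @return List with `users` (data frame: `patient_id`, `year`, `n_agents`,
#'   `acb_total`, `agents` semicolon-joined) and `classes` (data frame:
#'   `class`, `n`, `percent`).
#' @export
summarize_chronic_users <- function(records, year,
                                    catalog = default_catalog(),
                                    class_map = c(
                                      "Antidepressants" = "N06A",
                                      "Antipsychotics" = "N05A",
                                      "Drugs for urinary frequency and incontinence" = "G04BD"),
                                    min_events = 5L) {
  by_patient <- split(seq_len(nrow(records)), records$patient_id)
  rows <- list()
  for (pid in names(by_patient)) {
    hist <- records[by_patient[[pid]], , drop = FALSE]
    agents <- chronic_anticholinergics(hist, year, catalog, min_events)
    if (length(agents) == 0L) next
    rows[[pid]] <- data.frame(
      patient_id = pid, year = year, n_agents = length(agents),
      acb_total = acb_total(agents, catalog),
      agents = paste(agents, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  users <- if (length(rows) > 0L) {
    u <- do.call(rbind, rows)
    rownames(u) <- NULL
    u[order(u$patient_id, method = "radix"), , drop = FALSE]
  } else {
    data.frame(patient_id = character(0), year = integer(0),
               n_agents = integer(0), acb_total = integer(0),
               agents = character(0), stringsAsFactors = FALSE)
  }

  # patient-level class frequencies
  label_of <- function(code) {
    for (cl in names(class_map)) {
      if (startsWith(code, class_map[[cl]])) return(cl)
    }
    # fall back to the matching anticholinergic rule's label
    for (r in catalog$rules) {
      if (r$category == "ANTICHOLINERGIC" && any(startsWith(code, r$atc))) {
        return(r$label)
      }
    }
    code
  }
  n_users <- nrow(users)
  tallies <- list()
  for (i in seq_len(n_users)) {
    agents <- strsplit(users$agents[i], ";")[[1]]
    for (cl in unique(vapply(agents, label_of, ""))) {
      tallies[[cl]] <- c(tallies[[cl]], users$patient_id[i])
    }
  }
  classes <- if (length(tallies) > 0L) {
    cls <- names(tallies)
    n <- vapply(tallies, function(v) length(unique(v)), 0L)
    ord <- order(-n, cls, method = "radix")
    data.frame(class = cls[ord], n = as.integer(n[ord]),
               percent = percent(as.integer(n[ord]), n_users),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(class = character(0), n = integer(0), percent = numeric(0))
  }
  list(users = users, classes = classes)
}
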