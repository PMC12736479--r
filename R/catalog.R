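# Machine-readable PIM rule catalog: a versioned YAML rendering of the
# claims-operable subset of the 2019 Beers Criteria (drugs to avoid, drugs
# to use with caution, strong anticholinergics; ticlopidine retained), plus
# the anticholinergic cognitive burden (ACB) score table.

PIM_CATEGORIES <- c("AVOID", "CAUTION", "ANTICHOLINERGIC")

CONDITION_TYPES <- c("ALWAYS", "DURATION_OVER_8_WEEKS", "CO_DISPENSED_WITH",
                     "UNIT_DOSE_EXCEEDS", "ROUTE_IS", "FORM_IS",
                     "CHRONIC_USE", "ALL_OF")

ROUTE_LEVELS <- c("ORAL", "PARENTERAL", "TOPICAL", "TRANSDERMAL", "RECTAL",
                  "OPHTHALMIC", "OTHER", "UNKNOWN")
FORM_LEVELS <- c("TABLET", "CAPSULE", "SOLUTION", "CREAM", "PATCH",
                 "SUPPOSITORY", "DROPS", "OTHER", "UNKNOWN")

validate_condition <- function(cond, where) {
  if (!is.list(cond) || is.null(cond$type)) {
    return(sprintf("%s: condition must be a list with a 'type'", where))
  }
  if (!(cond$type %in% CONDITION_TYPES)) {
    return(sprintf("%s: unknown condition type '%s'", where, cond$type))
  }
  probs <- character(0)
  switch(cond$type,
    DURATION_OVER_8_WEEKS = {
      lo <- cond$min_gap_days %||% 56L
      hi <- cond$max_gap_days %||% 180L
      if (!(lo > 0 && hi > 0 && lo < hi)) {
        probs <- sprintf("%s: gap bounds must satisfy 0 < min < max", where)
      }
    },
    CO_DISPENSED_WITH = {
      if (length(cond$atc) == 0L || !all(is_valid_atc_prefix(cond$atc))) {
        probs <- sprintf("%s: partner ATC prefixes missing or invalid", where)
      }
      if ((cond$window_days %||% 90L) <= 0) {
        probs <- c(probs, sprintf("%s: window_days must be positive", where))
      }
    },
    UNIT_DOSE_EXCEEDS = {
      if (is.null(cond$mg_per_day) || cond$mg_per_day <= 0) {
        probs <- sprintf("%s: mg_per_day must be a positive number", where)
      }
    },
    ROUTE_IS = {
      if (is.null(cond$route) || !(cond$route %in% ROUTE_LEVELS)) {
        probs <- sprintf("%s: unknown route '%s'", where,
                         cond$route %||% "<missing>")
      }
    },
    FORM_IS = {
      if (is.null(cond$form) || !(cond$form %in% FORM_LEVELS)) {
        probs <- sprintf("%s: unknown form '%s'", where,
                         cond$form %||% "<missing>")
      }
    },
    CHRONIC_USE = {
      if ((cond$min_events %||% 5L) < 1) {
        probs <- sprintf("%s: min_events must be >= 1", where)
      }
    },
    ALL_OF = {
      if (length(cond$conditions) == 0L) {
        probs <- sprintf("%s: ALL_OF must contain at least one condition", where)
      } else {
        probs <- unlist(lapply(seq_along(cond$conditions), function(i) {
          validate_condition(cond$conditions[[i]],
                             sprintf("%s/ALL_OF[%d]", where, i))
        }))
      }
    }
  )
  probs
}

#' Validate a PIM catalog
#'
#' Checks structural invariants: unique rule ids, known categories, ATC
#' patterns cut at valid classification-level boundaries (1, 3, 4, 5 or 7
#' characters), well-formed applicability conditions, and a duplicate-free
#' ACB table with scores in 1-3.
#'
#' @param catalog A `"beers_catalog"` object (see [load_catalog()]).
#' @return Invisibly `TRUE`; otherwise an error listing every offending
#'   entry.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "beers_catalog"))
  probs <- character(0)
  ids <- vapply(catalog$rules, function(r) r$id %||% NA_character_, "")
  if (anyNA(ids)) probs <- c(probs, "rule without an id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    probs <- c(probs, paste0("duplicate rule_id: ", paste(dup, collapse = ", ")))
  }
  for (r in catalog$rules) {
    where <- paste0("rule '", r$id %||% "?", "'")
    if (!(r$category %||% "" ) %in% PIM_CATEGORIES) {
      probs <- c(probs, sprintf("%s: unknown category '%s'", where,
                                r$category %||% "<missing>"))
    }
    if (length(r$atc) == 0L) {
      probs <- c(probs, sprintf("%s: no ATC patterns", where))
    } else {
      bad <- r$atc[!is_valid_atc_prefix(r$atc)]
      if (length(bad) > 0L) {
        probs <- c(probs, sprintf("%s: invalid ATC pattern(s) %s", where,
                                  paste(bad, collapse = ", ")))
      }
    }
    if (is.null(r$label) || !nzchar(r$label)) {
      probs <- c(probs, sprintf("%s: missing label", where))
    }
    probs <- c(probs, validate_condition(r$condition %||% list(type = "ALWAYS"),
                                         where))
  }
  acb <- catalog$acb
  if (nrow(acb) > 0L) {
    bad <- acb$atc[!is_valid_atc_prefix(acb$atc)]
    if (length(bad) > 0L) {
      probs <- c(probs, paste0("invalid ACB ATC pattern(s): ",
                               paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(acb$atc)) {
      probs <- c(probs, paste0("duplicate ACB pattern(s): ",
                  paste(unique(acb$atc[duplicated(acb$atc)]), collapse = ", ")))
    }
    if (!all(acb$score %in% 1:3)) {
      probs <- c(probs, "ACB scores must be integers in 1-3")
    }
  }
  if (length(probs) > 0L) {
    stop("invalid catalog:\n  ", paste(probs, collapse = "\n  "))
  }
  invisible(TRUE)
}

catalog_from_list <- function(x) {
  rules <- lapply(x$rules, function(r) {
    r$atc <- toupper(as.character(unlist(r$atc)))
    cond <- r$condition %||% list(type = "ALWAYS")
    list(id = r$id, category = r$category, label = r$label, atc = r$atc,
         condition = cond, rationale = r$rationale %||% "")
  })
  ids <- vapply(rules, `[[`, "", "id")
  rules <- rules[order(ids, method = "radix")]
  names(rules) <- sort(ids, method = "radix")
  acb <- if (length(x$acb) > 0L) {
    data.frame(
      atc = toupper(vapply(x$acb, function(e) as.character(e$atc), "")),
      score = vapply(x$acb, function(e) as.integer(e$score), 0L),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(atc = character(0), score = integer(0))
  }
  structure(list(version = x$version %||% "unversioned",
                 rules = rules, acb = acb),
            class = "beers_catalog")
}

#' Load a PIM rule catalog from YAML
#'
#' The catalog file has top-level keys `version`, `rules` (each with `id`,
#' `category`, `label`, `atc` patterns and a `condition`) and `acb`
#' (ATC-pattern / score pairs). Rules are ordered by id on load so that rule
#' matching is deterministic. The loaded catalog is validated before being
#' returned.
#'
#' @param source Path to a catalog YAML file.
#' @return A `"beers_catalog"` object with elements `version`, `rules`
#'   (named list, ascending id) and `acb` (data frame `atc`, `score`).
#' @seealso [default_catalog()], [validate_catalog()], [write_catalog()]
#' @export
load_catalog <- function(source) {
  cat <- catalog_from_list(yaml::read_yaml(source))
  validate_catalog(cat)
  cat
}

#' Write a catalog back to YAML
#'
#' Serialization round-trips: `load_catalog()` of the written file yields a
#' catalog equal to the input.
#'
#' @param catalog A `"beers_catalog"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "beers_catalog"))
  x <- list(
    version = catalog$version,
    rules = lapply(unname(catalog$rules), function(r) {
      list(id = r$id, category = r$category, label = r$label,
           atc = as.list(r$atc), condition = r$condition,
           rationale = r$rationale)
    }),
    acb = lapply(seq_len(nrow(catalog$acb)), function(i) {
      list(atc = catalog$acb$atc[i], score = catalog$acb$score[i])
    })
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

pimscreen_env <- new.env(parent = emptyenv())

#' The shipped default catalog
#'
#' Loads (and caches) the catalog distributed with the package: the
#' claims-operable 2019 Beers subset covering PPIs (use beyond 8 weeks),
#' paroxetine, sulfonylureas, NSAIDs (chronic use and anticoagulant
#' co-dispensing), high-dose aspirin, amiodarone, tricyclic antidepressants
#' and ticlopidine among drugs to avoid; furosemide/torsemide, aldosterone
#' antagonists, diuretic combinations, hydrochlorothiazide, tramadol,
#' mirtazapine and antipsychotics among caution drugs; and eight strong
#' anticholinergics, each carrying an ACB score of 3.
#'
#' @return A validated `"beers_catalog"`.
#' @export
default_catalog <- function() {
  if (is.null(pimscreen_env$default_catalog)) {
    path <- system.file("extdata", "catalog-beers2019.yaml",
                        package = "pimscreen", mustWork = TRUE)
    pimscreen_env$default_catalog <- load_catalog(path)
  }
  pimscreen_env$default_catalog
}

#' Rules applicable to an ATC code
#'
#' Returns every catalog rule having at least one ATC pattern that is a
#' prefix of the query code, in ascending rule-id order. Matching is a pure
#' function of the code and the catalog; an unknown code yields an empty
#' list.
#'
#' @param atc_code A single ATC level-5 code (7 characters).
#' @param catalog A `"beers_catalog"`.
#' @return A (possibly empty) named list of rules.
#' @examples
#' \dontrun{
#' match_rules("N06AB05", default_catalog())  # paroxetine: avoid + anticholinergic
#' }
#' @export
match_rules <- function(atc_code, catalog) {
  stopifnot(inherits(catalog, "beers_catalog"),
            length(atc_code) == 1L, is_valid_atc_code(atc_code))
  hits <- vapply(catalog$rules,
                 function(r) any(startsWith(atc_code, r$atc)), NA)
  catalog$rules[hits]
}

#' ACB score of an ATC code
#'
#' Longest-prefix lookup in the catalog's anticholinergic cognitive burden
#' table; 0 when the code is not listed.
#'
#' @inheritParams match_rules
#' @return Integer score in 0-3.
#' @export
acb_score_of <- function(atc_code, catalog) {
  stopifnot(inherits(catalog, "beers_catalog"),
            length(atc_code) == 1L, is_valid_atc_code(atc_code))
  acb <- catalog$acb
  hit <- startsWith(atc_code, acb$atc)
  if (!any(hit)) return(0L)
  i <- which(hit)
  i <- i[which.max(nchar(acb$atc[i]))]
  as.integer(acb$score[i])
}

#' @export
print.beers_catalog <- function(x, ...) {
  cats <- table(factor(vapply(x$rules, `[[`, "", "category"),
                       levels = PIM_CATEGORIES))
  cat("PIM rule catalog '", x$version, "'\n", sep = "")
  cat("  rules: ", length(x$rules), " (",
      paste(sprintf("%s %d", names(cats), as.integer(cats)), collapse = ", "),
      ")\n", sep = "")
  cat("  ACB table entries:", nrow(x$acb), "\n")
  invisible(x)
}
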