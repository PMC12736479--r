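# Shared internal helpers: ATC syntax, prefix matching, dates.

# Valid ATC prefix lengths (classification level boundaries).
ATC_LEVEL_NCHAR <- c(1L, 3L, 4L, 5L, 7L)

#' @noRd
is_valid_atc_code <- function(x) {
  grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", x)
}

# A prefix is valid when it is the truncation of a well-formed level-5 code
# at a level boundary (1, 3, 4, 5 or 7 characters).
#' @noRd
is_valid_atc_prefix <- function(x) {
  full <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
  tpl <- c("^[A-Z]$", "^[A-Z][0-9]{2}$", "^[A-Z][0-9]{2}[A-Z]$",
           "^[A-Z][0-9]{2}[A-Z]{2}$", full)
  n <- match(nchar(x), ATC_LEVEL_NCHAR)
  ok <- !is.na(n)
  ok[ok] <- mapply(function(p, i) grepl(tpl[i], p), x[ok], n[ok])
  ok
}

#' @noRd
atc_matches_prefix <- function(codes, prefixes) {
  # TRUE for each code that starts with at least one of the prefixes
  if (length(prefixes) == 0L) return(rep(FALSE, length(codes)))
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

#' @noRd
parse_iso_date <- function(x, format = "%Y-%m-%d") {
  as.Date(as.character(x), format = format)
}

#' @noRd
year_of <- function(dates) {
  as.integer(format(dates, "%Y"))
}

# Half-up rounding (round() in R rounds half to even). Used for all
# printed percentages; the epsilon guards ratios of integers whose decimal
# representation sits an ulp below .5 in binary floating point.
#' @noRd
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  floor(x * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
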