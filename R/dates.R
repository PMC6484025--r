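MONTHS3 <- c("jan", "feb", "mar", "apr", "may", "jun",
             "jul", "aug", "sep", "oct", "nov", "dec")
MONTHS_FULL <- c("january", "february", "march", "april", "may", "june",
                 "july", "august", "september", "october", "november",
                 "december")

month_number <- function(tok) {
  tok <- tolower(tok)
  m <- match(substr(tok, 1, 3), MONTHS3)
  full <- match(tok, MONTHS_FULL)
  ifelse(!is.na(full), full,
         ifelse(!is.na(m) & (nchar(tok) == 3 | tok %in% MONTHS_FULL |
                               substr(MONTHS_FULL[pmax(m, 1)], 1, nchar(tok)) == tok),
                m, NA_integer_))
}

#' Parse collection dates under the unambiguity grammar
#'
#' Country-level differences in all-numeric date formats make `04/06/2017`
#' unreadable without outside knowledge: it is June 4 in one convention
#' and April 6 in another. The quality rules therefore accept only formats
#' that a reader anywhere can interpret: ISO 8601 (`2019-01-27`, optional
#' time), day-AlphaMonth-year (`4-Jun-2017`) and AlphaMonth day, year
#' (`Nov 12, 2015`), always with four-digit years. An all-numeric
#' non-ISO form is salvaged — with a warning — only when one field
#' exceeds 12 and so can only be the day (`25/06/2017`); when both
#' candidate fields are 12 or less the string is rejected as ambiguous.
#' Two-digit years are always rejected.
#'
#' @param x Character vector of date strings.
#' @return A tibble with one row per input: `input`, `date` (`Date`, `NA`
#'   unless `status` is `"ok"` or `"warning"`), `clock` (`"HH:MM"` or
#'   `"HH:MM:SS"` when a time was attached), `status` (one of `"ok"`,
#'   `"warning"`, `"ambiguous"`, `"two_digit_year"`, `"unparseable"`) and
#'   `detail` (human-readable explanation).
#' @examples
#' parse_date(c("2019-01-27", "4-Jun-2017", "Nov 12, 2015",
#'              "04/06/2017", "25/06/2017", "04/06/17"))
#' @export
parse_date <- function(x) {
  purrr::map_dfr(as.character(x), parse_date_one)
}

parse_date_one <- function(text) {
  out <- function(date = as.Date(NA), clock = NA_character_,
                  status, detail = "") {
    tibble(input = text, date = date, clock = clock,
           status = status, detail = detail)
  }
  s <- stringr::str_squish(text %||% "")
  if (is.na(s) || !nzchar(s)) {
    return(out(status = "unparseable", detail = "empty date"))
  }

  # split off a trailing clock time (ISO "T" or space separated)
  clock <- NA_character_
  m <- stringr::str_match(s, "^(.*?)[T ](\\d{1,2}:\\d{2}(:\\d{2})?)$")
  if (!is.na(m[1, 1]) && grepl("\\d{4}", m[1, 2])) {
    s <- stringr::str_squish(m[1, 2])
    clock <- m[1, 3]
  }

  # ISO 8601
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", s)) {
    d <- as.Date(s, format = "%Y-%m-%d")
    if (is.na(d)) {
      return(out(status = "unparseable", detail = "invalid calendar date"))
    }
    return(out(date = d, clock = clock, status = "ok", detail = "ISO 8601"))
  }

  # alphabetic-month forms: d-Mon-yyyy / d Mon yyyy / Mon d, yyyy
  toks <- stringr::str_split(gsub(",", " ", s), "[-/ ]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 3) {
    alpha <- grepl("^[A-Za-z]+$", toks)
    if (sum(alpha) == 1) {
      mon <- month_number(toks[alpha])
      nums <- suppressWarnings(as.integer(toks[!alpha]))
      digits <- nchar(toks[!alpha])
      if (is.na(mon) || any(is.na(nums))) {
        return(out(status = "unparseable", detail = "unrecognized month or day"))
      }
      yr_slot <- which(digits == 4)
      if (!length(yr_slot)) {
        return(out(status = "two_digit_year",
                   detail = "four-digit years are required"))
      }
      year <- nums[yr_slot[1]]
      day <- nums[-yr_slot[1]]
      if (length(day) != 1 || day < 1 || day > 31) {
        return(out(status = "unparseable", detail = "no valid day field"))
      }
      d <- as.Date(sprintf("%04d-%02d-%02d", year, mon, day), format = "%Y-%m-%d")
      if (is.na(d)) {
        return(out(status = "unparseable", detail = "invalid calendar date"))
      }
      return(out(date = d, clock = clock, status = "ok",
                 detail = "alphabetic month"))
    }
    if (all(!alpha)) {
      return(parse_numeric_date(text, toks, clock, out))
    }
  }
  out(status = "unparseable", detail = "unrecognized date form")
}

# all-numeric, non-ISO-dash forms
parse_numeric_date <- function(text, toks, clock, out) {
  nums <- suppressWarnings(as.integer(toks))
  digits <- nchar(toks)
  if (any(is.na(nums))) {
    return(out(status = "unparseable", detail = "non-numeric date field"))
  }
  yr_slot <- which(digits == 4)
  if (!length(yr_slot)) {
    return(out(status = "two_digit_year",
               detail = "four-digit years are required"))
  }
  year <- nums[yr_slot[1]]
  rest <- nums[-yr_slot[1]]
  if (yr_slot[1] == 1) {
    # year-first all-numeric (e.g. 2017/06/25): read as year/month/day but
    # warn — only the dashed ISO form is unambiguous by the rules
    d <- as.Date(sprintf("%04d-%02d-%02d", year, rest[1], rest[2]),
                 format = "%Y-%m-%d")
    if (is.na(d)) {
      return(out(status = "unparseable", detail = "invalid calendar date"))
    }
    return(out(date = d, clock = clock, status = "warning",
               detail = "year-first numeric date read as year/month/day"))
  }
  a <- rest[1]; b <- rest[2]
  if (a > 12 && b > 12) {
    return(out(status = "unparseable", detail = "no valid month field"))
  }
  if (a <= 12 && b <= 12) {
    return(out(status = "ambiguous",
               detail = sprintf(
                 "'%s' is ambiguous: day and month cannot be told apart", text)))
  }
  day <- if (a > 12) a else b
  mon <- if (a > 12) b else a
  d <- as.Date(sprintf("%04d-%02d-%02d", year, mon, day), format = "%Y-%m-%d")
  if (is.na(d)) {
    return(out(status = "unparseable", detail = "invalid calendar date"))
  }
  out(date = d, clock = clock, status = "warning",
      detail = sprintf("numeric date: %d > 12 forces the day slot", day))
}
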