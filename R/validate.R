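# Rule identifiers and their fixed default severities. R-rules are the
# data-quality standards (abbreviations, external keys, dates, format,
# styling/structure, precision, language); M-rules are minimum-information
# completeness; D-rules are record-level data checks. Errors are reserved
# for rules checkable without heuristics; heuristic rules warn.
RULE_SEVERITY <- c(
  R1_ABBREV = "warning",
  R2_EXTERNAL_KEY = "error",
  R3_DATE = "error",
  R4_FORMAT = "warning",
  R5_STYLING = "error",
  R6_PRECISION = "warning",
  R7_LANGUAGE = "warning",
  M1_CONTACT = "error",
  M2_STUDY_DESCRIPTION = "error",
  M3_IDENTIFICATION_METHOD = "error",
  M4_ABSENCE_POLICY = "error",
  M5_USAGE_RIGHTS = "error",
  M6_COLLECTION_METHOD = "error",
  D1_DUPLICATE_KEY = "error",
  D2_RELATIVE_ABUNDANCE = "error",
  D3_BAD_COORD = "error",
  D4_TIME_ORDER = "error"
)

# human names of the minimum-information concepts, used in messages
M_RULE_FIELD <- c(
  M1_CONTACT = "Contact details",
  M2_STUDY_DESCRIPTION = "Study description",
  M3_IDENTIFICATION_METHOD = "Species Identification Method",
  M4_ABSENCE_POLICY = "Not present vs zero information",
  M5_USAGE_RIGHTS = "Data usage information",
  M6_COLLECTION_METHOD = "Collection method"
)

empty_findings <- function() {
  tibble(rule_id = character(), severity = character(),
         row = integer(), column = character(), message = character())
}

add_finding <- function(findings, rule_id, severity = NULL,
                        row = NA_integer_, column = NA_character_,
                        message = "") {
  bind_rows(findings, tibble(
    rule_id = rule_id,
    severity = severity %||% unname(RULE_SEVERITY[rule_id]),
    row = as.integer(row), column = as.character(column),
    message = message
  ))
}

#' Validate a dataset against the quality and completeness rules
#'
#' Runs every rule exactly once over a dataset and returns a
#' machine-readable report. Problems are findings, never exceptions: a
#' dataset that loaded structurally always yields a report. Findings are
#' ordered deterministically by (rule id, row, column), and the dataset is
#' compliant exactly when it has no error-severity finding; warnings
#' (heuristic rules: abbreviations, coordinate precision, language,
#' format provenance) never block.
#'
#' @param dataset A [miread_dataset()].
#' @return An object of class `miread_report`: list with `findings`
#'   (tibble: `rule_id`, `severity`, `row`, `column`, `message`) and
#'   `is_compliant`. Use [tidy()] for the findings, [glance()] for a
#'   one-row summary.
#' @examples
#' ds <- generate_scenario(scenario_spec("long_trap", n_events = 3, seed = 1))
#' validate_dataset(ds)
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "miread_dataset"))
  f <- bind_rows(
    check_completeness(dataset),
    check_abbreviations(dataset),
    check_external_keys(dataset),
    check_dates(dataset),
    check_format(dataset),
    check_structure(dataset$raw),
    check_precision(dataset),
    check_language(dataset),
    check_records(dataset)
  )
  f <- arrange(f, .data$rule_id, .data$row, .data$column, .data$message)
  structure(list(findings = f,
                 is_compliant = !any(f$severity == "error")),
            class = "miread_report")
}

check_completeness <- function(dataset) {
  f <- empty_findings()
  meta <- dataset$metadata
  required <- c(M1_CONTACT = "contact",
                M2_STUDY_DESCRIPTION = "study_description",
                M3_IDENTIFICATION_METHOD = "identification_method",
                M4_ABSENCE_POLICY = "absence_policy",
                M5_USAGE_RIGHTS = "usage_rights")
  for (rid in names(required)) {
    val <- meta[[required[[rid]]]]
    if (is.null(val) || is.na(val) || !nzchar(stringr::str_squish(val))) {
      f <- add_finding(f, rid, column = required[[rid]],
                       message = sprintf(
                         "required resource metadata '%s' (%s) is missing",
                         required[[rid]], M_RULE_FIELD[[rid]]))
    }
  }
  missing_method <- which(is.na(dataset$events$collection_method) |
                            !nzchar(trimws(dataset$events$collection_method)))
  for (i in missing_method) {
    f <- add_finding(f, "M6_COLLECTION_METHOD", row = i,
                     column = "collection_method",
                     message = sprintf(
                       "event %s ('%s') has no collection method", i,
                       dataset$events$sample_id[i]))
  }
  f
}

# short all-caps or dotted tokens outside the unit/trap lexicon are treated
# as abbreviations; parenthesized unit annotations are exempt
abbrev_tokens <- function(text) {
  text <- gsub("\\([^()]*\\)", " ", text)        # units in parens exempt
  toks <- strsplit(text, "[ ,;:/]+")[[1]]
  toks <- toks[nzchar(toks)]
  dotted <- grepl("^[A-Za-z]{1,4}\\.$", toks)
  caps <- grepl("^[A-Z]{2,5}[0-9]?$", toks) &
    !toupper(toks) %in% ABBREV_LEXICON
  toks[dotted | caps]
}

check_abbreviations <- function(dataset) {
  f <- empty_findings()
  if (!is.null(dataset$raw)) {
    for (h in dataset$raw$header) {
      bad <- abbrev_tokens(h)
      if (length(bad)) {
        f <- add_finding(f, "R1_ABBREV", column = h,
                         message = sprintf(
                           "column name '%s' contains abbreviation '%s'",
                           h, bad[1]))
      }
    }
  }
  for (col in c("collection_method", "attractants")) {
    vals <- dataset$events[[col]]
    for (i in seq_along(vals)) {
      if (is.na(vals[i])) next
      bad <- abbrev_tokens(vals[i])
      if (length(bad)) {
        f <- add_finding(f, "R1_ABBREV", row = i, column = col,
                         message = sprintf(
                           "value '%s' contains abbreviation '%s'",
                           vals[i], bad[1]))
      }
    }
  }
  f
}

looks_like_code <- function(x) {
  grepl("^[A-Za-z]{0,4}[_-]?[0-9]+$", x)
}

check_external_keys <- function(dataset) {
  f <- empty_findings()
  ev <- dataset$events
  no_coords <- is.na(ev$latitude) & is.na(ev$longitude)
  for (i in which(no_coords)) {
    loc <- ev$locality_text[i]
    if (is.na(loc) || !nzchar(loc) || looks_like_code(loc)) {
      f <- add_finding(f, "R2_EXTERNAL_KEY", row = i, column = "locality_text",
                       message = sprintf(
                         paste0("event %s has no coordinates and location '%s' ",
                                "is an opaque identifier needing an external key"),
                         ev$sample_id[i], loc %||% ""))
    }
  }
  rec <- dataset$records
  coded <- which(looks_like_code(rec$name))
  for (i in coded) {
    f <- add_finding(f, "R2_EXTERNAL_KEY", row = i, column = "name",
                     message = sprintf(
                       "taxon '%s' is a code, not a scientific name",
                       rec$name[i]))
  }
  f
}

check_dates <- function(dataset) {
  f <- empty_findings()
  ev <- dataset$events
  for (side in c("start", "end")) {
    status <- ev[[paste0(side, "_status")]]
    raw <- ev[[paste0(side, "_raw")]]
    for (i in seq_along(status)) {
      if (is.na(status[i]) || status[i] == "ok") next
      sev <- if (status[i] == "warning") "warning" else "error"
      f <- add_finding(f, "R3_DATE", severity = sev, row = i,
                       column = paste0(side, "_time"),
                       message = sprintf("date '%s' is %s", raw[i],
                                         status[i]))
    }
  }
  f
}

# machine-readability is enforced at read time; provenance findings from
# ingestion (encoding fallback, layout detection, auto-generated ids,
# unbound columns) pass through here
check_format <- function(dataset) {
  dataset$ingest_findings
}

check_structure <- function(raw) {
  f <- empty_findings()
  if (is.null(raw)) return(f)
  for (fi in seq_len(nrow(raw$findings))) {
    if (raw$findings$rule_id[fi] == "R5_STYLING") {
      f <- bind_rows(f, raw$findings[fi, ])
    }
  }
  date_col <- which(grepl("date|start", raw$header, ignore.case = TRUE))[1]
  for (i in seq_along(raw$rows)) {
    cells <- trimws(raw$rows[[i]])
    if (nzchar(cells[1]) && length(cells) > 1 && all(!nzchar(cells[-1]))) {
      f <- add_finding(f, "R5_STYLING", row = i,
                       message = sprintf(
                         "row %d ('%s') is a subsection heading, not data",
                         i, cells[1]))
    } else if (!is.na(date_col) && !nzchar(cells[date_col]) &&
               any(nzchar(cells[-date_col]))) {
      f <- add_finding(f, "R5_STYLING", row = i,
                       column = raw$header[date_col],
                       message = sprintf(
                         paste0("row %d leaves '%s' blank and is only ",
                                "interpretable via neighbouring rows"),
                         i, raw$header[date_col]))
    }
  }
  f
}

# stated precision: digits after the decimal point as written (trailing
# zeros are significant in a reported coordinate)
decimal_places <- function(raw) {
  ifelse(is.na(raw) | !grepl("\\.", raw), 0L,
         nchar(sub("^[^.]*\\.", "", raw)))
}

# declared obfuscation like "rounded to 0.1 degree" implies a precision in
# decimal places; emitted coordinates must not be finer
declared_obfuscation_places <- function(text) {
  m <- stringr::str_match(tolower(text), "0\\.(0*1)")[, 2]
  if (is.na(m)) return(NA_integer_)
  nchar(m)
}

check_precision <- function(dataset) {
  f <- empty_findings()
  ev <- dataset$events
  obf <- dataset$metadata$gps_obfuscation
  declared <- if (nzchar(obf)) declared_obfuscation_places(obf) else NA_integer_
  for (col in c("lat_raw", "lon_raw")) {
    raw <- ev[[col]]
    dp <- decimal_places(raw)
    name <- if (col == "lat_raw") "latitude" else "longitude"
    for (i in seq_along(raw)) {
      if (is.na(raw[i]) || !nzchar(raw[i])) next
      if (!nzchar(obf) && dp[i] < 2) {
        f <- add_finding(f, "R6_PRECISION", row = i, column = name,
                         message = sprintf(
                           paste0("%s '%s' has %d decimal place(s) and no ",
                                  "obfuscation is declared in the metadata"),
                           name, raw[i], dp[i]))
      } else if (!is.na(declared) && dp[i] > declared) {
        f <- add_finding(f, "R6_PRECISION", severity = "error",
                         row = i, column = name,
                         message = sprintf(
                           paste0("%s '%s' is finer than the declared ",
                                  "obfuscated precision (%d decimal places)"),
                           name, raw[i], declared))
      }
    }
  }
  f
}

check_language <- function(dataset) {
  f <- empty_findings()
  headers <- if (!is.null(dataset$raw)) dataset$raw$header else character()
  info_keys <- unique(unlist(lapply(dataset$events$additional_info, names)))
  for (h in c(headers, info_keys)) {
    if (is.na(h) || !nzchar(h)) next
    if (any(utf8ToInt(h) > 127L)) {
      f <- add_finding(f, "R7_LANGUAGE", column = h,
                       message = sprintf(
                         "field name '%s' is not ASCII/English; prefer English field names",
                         h))
    }
  }
  f
}

check_records <- function(dataset) {
  f <- empty_findings()
  rec <- dataset$records
  ev <- dataset$events

  keys <- canonical_key(rec)
  for (i in which(duplicated(keys))) {
    f <- add_finding(f, "D1_DUPLICATE_KEY", row = i, column = "record",
                     message = sprintf(
                       "record %d duplicates the (event, taxon, sex, stage, unit) cell of record %d",
                       i, match(keys[i], keys)))
  }

  rel <- grepl("relative|proportion|percent|%|per ?cent|index",
               rec$unit, ignore.case = TRUE)
  for (i in which(rel)) {
    f <- add_finding(f, "D2_RELATIVE_ABUNDANCE", row = i, column = "unit",
                     message = sprintf(
                       "unit '%s' declares a derived relative abundance; raw quantities are required",
                       rec$unit[i]))
  }

  bad_lat <- !is.na(ev$latitude) & (ev$latitude < -90 | ev$latitude > 90)
  bad_lon <- !is.na(ev$longitude) & (ev$longitude < -180 | ev$longitude > 180)
  for (i in which(bad_lat)) {
    f <- add_finding(f, "D3_BAD_COORD", row = i, column = "latitude",
                     message = sprintf("latitude %s is outside [-90, 90]",
                                       ev$lat_raw[i]))
  }
  for (i in which(bad_lon)) {
    f <- add_finding(f, "D3_BAD_COORD", row = i, column = "longitude",
                     message = sprintf("longitude %s is outside [-180, 180]",
                                       ev$lon_raw[i]))
  }

  bad_order <- !is.na(ev$start_date) & !is.na(ev$end_date) &
    event_instant(ev$start_date, ev$start_clock) >
    event_instant(ev$end_date, ev$end_clock)
  for (i in which(bad_order)) {
    f <- add_finding(f, "D4_TIME_ORDER", row = i, column = "start_time",
                     message = sprintf(
                       "event %s starts (%s %s) after it ends (%s %s)",
                       ev$sample_id[i], ev$start_date[i],
                       ev$start_clock[i] %||% "", ev$end_date[i],
                       ev$end_clock[i] %||% ""))
  }
  f
}

#' @export
print.miread_report <- function(x, ...) {
  verdict <- if (x$is_compliant) "COMPLIANT" else "NOT COMPLIANT"
  n_err <- sum(x$findings$severity == "error")
  n_warn <- sum(x$findings$severity == "warning")
  cat(sprintf("<miread_report> %s (%d error(s), %d warning(s))\n",
              verdict, n_err, n_warn))
  shown <- filter(x$findings, .data$severity != "info")
  for (i in seq_len(min(nrow(shown), 20))) {
    cat(sprintf("  [%s] %s: %s\n", shown$severity[i], shown$rule_id[i],
                shown$message[i]))
  }
  if (nrow(shown) > 20) cat(sprintf("  ... and %d more\n", nrow(shown) - 20))
  invisible(x)
}

#' @describeIn validate_dataset Findings as a tibble (one row per finding).
#' @param x A `miread_report`.
#' @param ... Unused.
#' @method tidy miread_report
#' @export
tidy.miread_report <- function(x, ...) {
  x$findings
}

#' @describeIn validate_dataset One-row summary: counts by severity and the
#'   compliance verdict.
#' @method glance miread_report
#' @export
glance.miread_report <- function(x, ...) {
  tibble(
    n_findings = nrow(x$findings),
    n_errors = sum(x$findings$severity == "error"),
    n_warnings = sum(x$findings$severity == "warning"),
    n_rules_triggered = dplyr::n_distinct(
      x$findings$rule_id[x$findings$severity != "info"]),
    is_compliant = x$is_compliant
  )
}

#' Serialize a validation report to JSON
#'
#' Byte-stable serialization for diffing and CI: identical datasets yield
#' identical report files.
#'
#' @param report A `miread_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_json <- function(report, path = NULL) {
  payload <- list(
    is_compliant = report$is_compliant,
    findings = report$findings
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, na = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}

#' Plot a validation report
#'
#' Bar chart of findings per rule, filled by severity — a quick visual
#' answer to "what is wrong with this submission".
#'
#' @param object A `miread_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot miread_report
#' @export
autoplot.miread_report <- function(object, ...) {
  df <- filter(object$findings, .data$severity != "info")
  if (!nrow(df)) {
    df <- tibble(rule_id = "none", severity = "none")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rule_id, fill = .data$severity)) +
    ggplot2::geom_bar() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(error = "#b2182b",
                                          warning = "#ef8a62",
                                          none = "grey80"),
                               drop = TRUE) +
    ggplot2::labs(x = NULL, y = "findings",
                  title = if (object$is_compliant)
                    "Compliant submission" else "Non-compliant submission") +
    ggplot2::theme_minimal()
}
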