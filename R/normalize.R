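CANONICAL_COLUMNS <- c(
  "sample_id", "sample_name", "start_date", "start_clock", "end_date",
  "end_clock", "latitude", "longitude", "locality_text",
  "collection_method", "attractants", "collection_area",
  "taxon_rank", "taxon_name", "sex", "life_stage", "value", "unit"
)

#' Convert a dataset to canonical long form
#'
#' Canonical form is long layout with records unique on their
#' [canonical_key()]: one row per (event, taxon, sex, life stage, unit)
#' cell. Zeros asserted by the source are kept as value-0 records —
#' dropping them would erase the zero-versus-unknown distinction the
#' metadata declares. Two source columns that collapse onto one canonical
#' key cannot be represented and raise a duplicate-key error.
#'
#' @param dataset A [miread_dataset()] in any layout.
#' @return The dataset with `layout = "long"` and unique record keys.
#' @export
wide_to_long <- function(dataset) {
  stopifnot(inherits(dataset, "miread_dataset"))
  keys <- canonical_key(dataset$records)
  if (anyDuplicated(keys)) {
    dup <- dataset$records[duplicated(keys), ]
    abort(sprintf(
      "duplicate canonical key: two cells collapse onto (%s, %s, %s, %s)",
      dup$event_ref[1], dup$name[1], dup$sex[1], dup$life_stage[1]),
      class = "miread_duplicate_key")
  }
  dataset$layout <- "long"
  dataset
}

# deterministic wide column label: "name[, sex][, stage] (unit)"
wide_header <- function(name, sex, life_stage, unit) {
  ann <- c(if (sex != "unknown") sex,
           if (life_stage != "unknown") life_stage)
  paste0(paste(c(name, ann), collapse = ", "), " (", unit, ")")
}

#' Pivot a canonical dataset to wide layout
#'
#' One row per sampling event, one column per (taxon, sex, life stage,
#' unit) combination, labelled by the convention
#' `Taxon name[, sex][, life stage] (unit)` and ordered alphabetically by
#' (name, stage, sex) so that output is deterministic. Cells are empty
#' only where no record exists; the resulting table round-trips through
#' [bind_columns()]/[wide_to_long()] without loss.
#'
#' @param dataset A canonical [miread_dataset()].
#' @return A tibble: event columns then taxon columns.
#' @export
long_to_wide <- function(dataset) {
  dataset <- wide_to_long(dataset)  # asserts canonical keys
  ev <- select(dataset$events, -"additional_info")
  info_keys <- unique(unlist(lapply(dataset$events$additional_info, names)))
  for (k in info_keys) {
    ev[[k]] <- vapply(dataset$events$additional_info, function(ai) {
      if (k %in% names(ai)) ai[[k]] else NA_character_
    }, character(1))
  }
  ev <- select(ev, -dplyr::any_of(c("start_raw", "end_raw", "start_status",
                                    "end_status", "lat_raw", "lon_raw")))

  rec <- dataset$records
  if (!nrow(rec)) return(ev)
  rec <- mutate(rec, .header = purrr::pmap_chr(
    list(.data$name, .data$sex, .data$life_stage, .data$unit), wide_header))
  order_key <- distinct(rec, .data$.header, .data$name, .data$life_stage,
                        .data$sex)
  order_key <- arrange(order_key, .data$name, .data$life_stage, .data$sex)
  wide <- tidyr::pivot_wider(
    select(rec, "event_ref", ".header", "value"),
    names_from = ".header", values_from = "value")
  wide <- select(wide, "event_ref", dplyr::all_of(order_key$.header))
  out <- left_join(ev, wide, by = c(sample_id = "event_ref"))
  out
}

#' Split composite stage/sex records into linked per-class records
#'
#' Different life stages and sexes are preferably documented as separate
#' records, linked by a shared sample name rather than merged into one
#' row. This takes records whose `additional_info`-style composite
#' annotation carries per-class counts and is a no-op on already-split
#' data. A composite count with no per-class values cannot be
#' apportioned without inventing data: the record is kept composite
#' (`sex`/`life_stage` = `"mixed"`) and the returned attribute
#' `"split_warnings"` notes it.
#'
#' @param dataset A [miread_dataset()].
#' @param counts Optional tibble of per-class counts to split by:
#'   columns `event_ref`, `name`, `life_stage` and/or `sex`, `value`,
#'   optional `rank` (per-class rank may differ: genus-level larvae,
#'   species-level adults) and `unit`.
#' @return The dataset with split records; splits from one composite
#'   share that record's `sample_name`.
#' @export
split_linked_records <- function(dataset, counts = NULL) {
  stopifnot(inherits(dataset, "miread_dataset"))
  if (is.null(counts) || !nrow(counts)) return(dataset)
  rec <- dataset$records
  warnings <- character()
  keep <- rep(TRUE, nrow(rec))
  new <- list()
  for (i in seq_len(nrow(rec))) {
    if (!(rec$life_stage[i] == "mixed" || rec$sex[i] == "mixed")) next
    parts <- filter(counts,
                    .data$event_ref == rec$event_ref[i],
                    tolower(.data$name) == tolower(rec$name[i]) |
                      vapply(strsplit(.data$name, " "), `[[`, character(1), 1) ==
                      strsplit(rec$name[i], " ")[[1]][1])
    if (!nrow(parts)) {
      warnings <- c(warnings, sprintf(
        "record %d ('%s', %s) has no per-class counts; kept composite",
        i, rec$name[i], rec$life_stage[i]))
      next
    }
    if (abs(sum(parts$value) - rec$value[i]) > 1e-9) {
      warnings <- c(warnings, sprintf(
        "record %d: per-class counts sum to %s, composite says %s; kept composite",
        i, sum(parts$value), rec$value[i]))
      next
    }
    keep[i] <- FALSE
    for (j in seq_len(nrow(parts))) {
      nm <- parts$name[j]
      rk <- if ("rank" %in% names(parts) && !is.na(parts$rank[j])) {
        parts$rank[j]
      } else if (length(strsplit(nm, " ")[[1]]) >= 2) "species" else "genus"
      new[[length(new) + 1L]] <- tibble(
        event_ref = rec$event_ref[i], rank = rk, name = nm,
        sex = if ("sex" %in% names(parts)) normalize_sex(parts$sex[j])
              else rec$sex[i],
        life_stage = if ("life_stage" %in% names(parts))
          normalize_life_stage(parts$life_stage[j]) else rec$life_stage[i],
        value = parts$value[j],
        unit = if ("unit" %in% names(parts)) parts$unit[j] else rec$unit[i],
        sample_name = rec$sample_name[i]
      )
    }
  }
  dataset$records <- bind_rows(rec[keep, ], bind_rows(new))
  attr(dataset, "split_warnings") <- warnings
  dataset
}

#' Keep host descriptors on the event, not the arthropod
#'
#' Ectoparasite surveys record attributes of the examined host (e.g. the
#' sex of a trapped mouse). Those belong in the sampling event's
#' additional information, never in the arthropod record's own sex or
#' life-stage fields — conflating host sex with parasite sex is a classic
#' mapping error. This moves any record-level columns whose names mark
#' them as host attributes (prefix `"host"`) into the owning event's
#' `additional_info`, and errors if a mapping bound a host column onto the
#' arthropod `sex`/`life_stage` concepts.
#'
#' @param dataset A [miread_dataset()].
#' @param host_fields Named character vector per event
#'   (`sample_id -> value`) or a tibble with columns `sample_id`, `key`,
#'   `value` to attach.
#' @return The dataset with host context on events.
#' @export
attach_host_context <- function(dataset, host_fields = NULL) {
  stopifnot(inherits(dataset, "miread_dataset"))
  if (!is.null(dataset$raw)) {
    bound <- names(which(vapply(
      dataset$raw$header, function(h) grepl("^host", h, ignore.case = TRUE),
      logical(1))))
    concepts <- attr(dataset, "bound_concepts")
    if (!is.null(concepts) &&
        any(concepts[bound] %in% c("sex", "life_stage"))) {
      abort("host attribute column bound to the arthropod sex/life_stage concept",
            class = "miread_invariant")
    }
  }
  if (is.null(host_fields)) return(dataset)
  if (!is.data.frame(host_fields)) {
    host_fields <- tibble(sample_id = names(host_fields),
                          key = "host sex", value = unname(host_fields))
  }
  for (j in seq_len(nrow(host_fields))) {
    i <- match(host_fields$sample_id[j], dataset$events$sample_id)
    if (is.na(i)) next
    ai <- dataset$events$additional_info[[i]]
    ai[[host_fields$key[j]]] <- host_fields$value[j]
    dataset$events$additional_info[[i]] <- ai
  }
  dataset
}

#' Write a dataset as a wide-layout CSV
#'
#' Serializes the [long_to_wide()] pivot: one row per event, one column
#' per taxon group under the `Taxon name[, sex][, life stage] (unit)`
#' header convention, ISO 8601 dates, UTF-8. The file re-ingests through
#' [read_table()] + [bind_columns()] as a wide-layout dataset with the
#' same canonical records.
#'
#' @param dataset A canonical [miread_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wide_csv <- function(dataset, path) {
  wide <- long_to_wide(dataset)
  tab <- wide
  # emit coordinates as originally stated (precision is meaningful) and
  # dates with their clock times attached (parseable as one timestamp)
  idx <- match(tab$sample_id, dataset$events$sample_id)
  tab$latitude <- dataset$events$lat_raw[idx]
  tab$longitude <- dataset$events$lon_raw[idx]
  tab$start_date <- paste0(
    format(tab$start_date, "%Y-%m-%d"),
    ifelse(is.na(tab$start_clock), "", paste0(" ", tab$start_clock)))
  tab$end_date <- paste0(
    format(tab$end_date, "%Y-%m-%d"),
    ifelse(is.na(tab$end_clock), "", paste0(" ", tab$end_clock)))
  tab <- select(tab, -"start_clock", -"end_clock")
  tab <- rename(tab, start_time = "start_date", end_time = "end_date")
  for (col in names(tab)) {
    if (is.numeric(tab[[col]])) {
      tab[[col]] <- ifelse(is.na(tab[[col]]), NA_character_,
                           format_value(tab[[col]]))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(csv_quote(names(tab)), collapse = ","), con,
             useBytes = TRUE)
  for (i in seq_len(nrow(tab))) {
    writeLines(paste(csv_quote(as.character(unlist(tab[i, ]))),
                     collapse = ","), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Write / read the canonical long interchange CSV
#'
#' The package's interchange format: UTF-8, comma-delimited, ISO 8601
#' dates, one header row, fixed documented column set (event fields, then
#' taxon fields, then value and unit), plus one trailing column per
#' distinct additional-information key. A dataset written and re-read
#' round-trips exactly.
#'
#' @param dataset A [miread_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_canonical_csv <- function(dataset, path) {
  tab <- canonical_table(dataset)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(csv_quote(names(tab)), collapse = ","), con,
             useBytes = TRUE)
  for (i in seq_len(nrow(tab))) {
    writeLines(paste(csv_quote(as.character(unlist(tab[i, ]))),
                     collapse = ","), con, useBytes = TRUE)
  }
  invisible(path)
}

csv_quote <- function(x) {
  x[is.na(x)] <- ""
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

canonical_table <- function(dataset) {
  ev <- dataset$events
  rec <- dataset$records
  joined <- left_join(rec, ev, by = c(event_ref = "sample_id"),
                      suffix = c("", ".ev"))
  info_keys <- sort(unique(unlist(lapply(ev$additional_info, names))))
  out <- tibble(
    sample_id = rec$event_ref,
    sample_name = joined$sample_name.ev,
    # a date that failed the unambiguity grammar is written back verbatim:
    # rewriting it as ISO would launder the submission
    start_date = ifelse(joined$start_status == "ok" | is.na(joined$start_status),
                        format(joined$start_date, "%Y-%m-%d"),
                        joined$start_raw),
    start_clock = joined$start_clock,
    end_date = ifelse(joined$end_status == "ok" | is.na(joined$end_status),
                      format(joined$end_date, "%Y-%m-%d"),
                      joined$end_raw),
    end_clock = joined$end_clock,
    latitude = joined$lat_raw,
    longitude = joined$lon_raw,
    locality_text = joined$locality_text,
    collection_method = joined$collection_method,
    attractants = joined$attractants,
    collection_area = joined$collection_area,
    taxon_rank = rec$rank,
    taxon_name = rec$name,
    sex = rec$sex,
    life_stage = rec$life_stage,
    value = format_value(rec$value),
    unit = rec$unit
  )
  for (k in info_keys) {
    out[[k]] <- vapply(joined$additional_info, function(ai) {
      if (k %in% names(ai)) ai[[k]] else NA_character_
    }, character(1))
  }
  out
}

format_value <- function(v) {
  ifelse(v == round(v), format(v, scientific = FALSE, trim = TRUE),
         as.character(v))
}

#' @rdname write_canonical_csv
#' @param metadata Metadata to attach to the re-read dataset (the CSV
#'   carries data only; resource metadata travels separately).
#' @export
read_canonical_csv <- function(path, metadata = miread_metadata()) {
  raw <- read_table(path, delimiter = ",")
  extra <- setdiff(raw$header, CANONICAL_COLUMNS)
  bindings <- c(
    setNames(c("sample_id", "sample_name", "start_time", "end_time",
               "latitude", "longitude", "locality_text",
               "collection_method", "attractants", "collection_area",
               "taxon_rank", "taxon", "sex", "life_stage", "value", "unit"),
             c("sample_id", "sample_name", "start_date", "end_date",
               "latitude", "longitude", "locality_text",
               "collection_method", "attractants", "collection_area",
               "taxon_rank", "taxon_name", "sex", "life_stage", "value",
               "unit")),
    c(start_clock = "ignore", end_clock = "ignore"),
    setNames(rep("additional_info", length(extra)), extra)
  )
  ds <- bind_columns(raw, field_mapping(layout = "long", bindings = bindings),
                     metadata = metadata)
  # clock times are carried in their own columns
  clocks <- dplyr::bind_cols(
    start = vapply(raw$rows, function(r) r[match("start_clock", raw$header)],
                   character(1)),
    end = vapply(raw$rows, function(r) r[match("end_clock", raw$header)],
                 character(1)))
  first_row <- match(ds$events$sample_id,
                     vapply(raw$rows, function(r)
                       r[match("sample_id", raw$header)], character(1)))
  ds$events$start_clock <- dplyr::na_if(clocks$start[first_row], "")
  ds$events$end_clock <- dplyr::na_if(clocks$end[first_row], "")
  ds
}
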