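#' Resource-level (dataset) metadata
#'
#' A MIReAD submission has two components: resource metadata and data
#' records. This constructor builds the metadata component — the
#' minimum information a reader needs to reuse the dataset without
#' contacting its authors. For a dataset to be judged compliant,
#' `contact`, `study_description`, `identification_method`,
#' `absence_policy` and `usage_rights` must be non-empty; the remaining
#' fields are optional context.
#'
#' @param contact Person/organization plus a reachable address.
#' @param study_description Free text describing the experiment or
#'   collection design.
#' @param citations Character vector of citations (may be empty).
#' @param identification_method How specimens were identified to taxon.
#' @param absence_policy One of `"explicit_zeros"`,
#'   `"absent_means_unknown"`, `"absent_means_zero"` — whether a missing
#'   taxon/event combination means an asserted zero, an unknown, or is
#'   never missing because zeros are written out.
#' @param absence_note Optional free-text elaboration of the policy.
#' @param gps_obfuscation Free text describing deliberate coordinate
#'   degradation (e.g. "coordinates rounded to 0.1 degree for privacy");
#'   empty means coordinates are at full precision.
#' @param datum Geodetic datum label for the coordinates (default WGS84).
#' @param usage_rights Free text or a license identifier.
#' @param language IETF-style language tag for the submission.
#' @return An object of class `miread_metadata` (a named list).
#' @examples
#' meta <- miread_metadata(
#'   contact = "J. Doe, j.doe@example.org",
#'   study_description = "Weekly light-trap monitoring, 2017 season",
#'   identification_method = "Morphological keys (Darsie & Ward)",
#'   absence_policy = "explicit_zeros",
#'   usage_rights = "CC-BY 4.0"
#' )
#' @export
miread_metadata <- function(contact = "",
                            study_description = "",
                            citations = character(),
                            identification_method = "",
                            absence_policy = c("absent_means_unknown",
                                               "explicit_zeros",
                                               "absent_means_zero"),
                            absence_note = "",
                            gps_obfuscation = "",
                            datum = "WGS84",
                            usage_rights = "",
                            language = "en") {
  absence_policy <- match.arg(absence_policy)
  out <- list(
    contact = as.character(contact)[1],
    study_description = as.character(study_description)[1],
    citations = as.character(citations),
    identification_method = as.character(identification_method)[1],
    absence_policy = absence_policy,
    absence_note = as.character(absence_note)[1],
    gps_obfuscation = as.character(gps_obfuscation)[1],
    datum = as.character(datum)[1],
    usage_rights = as.character(usage_rights)[1],
    language = as.character(language)[1]
  )
  structure(out, class = "miread_metadata")
}

#' @export
print.miread_metadata <- function(x, ...) {
  cat("<miread_metadata>\n")
  for (f in c("contact", "study_description", "identification_method",
              "absence_policy", "usage_rights")) {
    val <- x[[f]]
    cat(sprintf("  %-22s %s\n", f,
                if (nzchar(val)) val else "<missing>"))
  }
  if (nzchar(x$gps_obfuscation)) {
    cat(sprintf("  %-22s %s\n", "gps_obfuscation", x$gps_obfuscation))
  }
  invisible(x)
}

empty_events <- function() {
  tibble(
    sample_id = character(), sample_name = character(),
    start_date = as.Date(character()), start_clock = character(),
    end_date = as.Date(character()), end_clock = character(),
    start_raw = character(), end_raw = character(),
    start_status = character(), end_status = character(),
    latitude = double(), longitude = double(),
    lat_raw = character(), lon_raw = character(),
    locality_text = character(), collection_method = character(),
    attractants = character(), collection_area = character(),
    additional_info = list()
  )
}

empty_records <- function() {
  tibble(
    event_ref = character(), rank = character(), name = character(),
    sex = character(), life_stage = character(),
    value = double(), unit = character(), sample_name = character()
  )
}

#' Construct a single sampling event
#'
#' One sampling event is one collection act: a trap night, a tick drag, an
#' examination of one host. Events carry when, where and how; observed
#' quantities live in abundance records that reference the event by
#' `sample_id`. The constructor enforces the event invariants (coordinate
#' ranges, start before end) and names the violated invariant on failure;
#' lower-level ingestion builds events without these checks so that the
#' validator can report problems as findings instead.
#'
#' @param sample_id Opaque stable identifier, unique per event.
#' @param start_date,end_date Collection start/end dates (`Date` or
#'   ISO-8601 strings). `end_date` defaults to `start_date`
#'   (cross-sectional / instantaneous sampling).
#' @param start_clock,end_clock Optional clock times, `"HH:MM"`.
#' @param latitude,longitude Decimal degrees (WGS84 unless the metadata
#'   datum says otherwise).
#' @param sample_name Optional human label used to link split records.
#' @param locality_text Optional free-text locality.
#' @param collection_method Trap/drag/flag/host-search description.
#' @param attractants Optional attractants used.
#' @param collection_area Optional effort/area, magnitude plus unit.
#' @param additional_info Named character vector of free-text attributes
#'   (e.g. `c("sub-location" = "cattle shed", "host sex" = "female")`).
#' @return A one-row events tibble.
#' @examples
#' sampling_event("ev1", "2017-06-04", latitude = 41.66, longitude = -91.53,
#'                collection_method = "New Jersey light trap")
#' @export
sampling_event <- function(sample_id,
                           start_date,
                           end_date = start_date,
                           start_clock = NA_character_,
                           end_clock = NA_character_,
                           latitude = NA_real_,
                           longitude = NA_real_,
                           sample_name = NA_character_,
                           locality_text = NA_character_,
                           collection_method = NA_character_,
                           attractants = NA_character_,
                           collection_area = NA_character_,
                           additional_info = character()) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date)) {
    abort("invariant violated: start_time requires a date",
          class = "miread_invariant")
  }
  if (!is.na(latitude) && (latitude < -90 || latitude > 90)) {
    abort("invariant violated: latitude must lie in [-90, 90]",
          class = "miread_invariant")
  }
  if (!is.na(longitude) && (longitude < -180 || longitude > 180)) {
    abort("invariant violated: longitude must lie in [-180, 180]",
          class = "miread_invariant")
  }
  if (!is.na(end_date) &&
      event_instant(start_date, start_clock) >
      event_instant(end_date, end_clock)) {
    abort("invariant violated: start_time must not exceed end_time",
          class = "miread_invariant")
  }
  tibble(
    sample_id = as.character(sample_id),
    sample_name = as.character(sample_name),
    start_date = start_date, start_clock = as.character(start_clock),
    end_date = end_date, end_clock = as.character(end_clock),
    start_raw = format(start_date, "%Y-%m-%d"),
    end_raw = format(end_date, "%Y-%m-%d"),
    start_status = "ok", end_status = "ok",
    latitude = as.numeric(latitude), longitude = as.numeric(longitude),
    lat_raw = coord_raw(latitude), lon_raw = coord_raw(longitude),
    locality_text = as.character(locality_text),
    collection_method = as.character(collection_method),
    attractants = as.character(attractants),
    collection_area = as.character(collection_area),
    additional_info = list(additional_info)
  )
}

coord_raw <- function(x) {
  ifelse(is.na(x), NA_character_,
         sub("0+$", "", sprintf("%.6f", as.numeric(x))))
}

# sortable instant; missing clocks count as midnight so same-day events with
# no times compare equal
event_instant <- function(date, clock) {
  clock <- ifelse(is.na(clock) | !nzchar(clock), "00:00", clock)
  paste(format(date, "%Y-%m-%d"), clock)
}

#' Construct a single abundance record
#'
#' One record is one observed quantity: a (event, taxon, sex, life stage,
#' unit) cell in canonical long form. Values must be raw quantities —
#' relative abundances are derived values and declaring such a unit is a
#' compliance error at validation time; an outright negative value is
#' rejected here.
#'
#' @param event_ref `sample_id` of the sampling event the observation
#'   belongs to.
#' @param name Scientific name at the most precise rank asserted; passed
#'   through [resolve_rank()] unless `rank` is given.
#' @param value Non-negative observed quantity.
#' @param unit Unit of measurement/observation (e.g. `"individuals"`).
#' @param sex,life_stage Labels, normalized onto the canonical levels.
#' @param rank Optional explicit rank, overriding token-count resolution.
#' @param sample_name Optional linking label shared by split records.
#' @return A one-row records tibble.
#' @examples
#' abundance_record("ev1", "Aedes aegypti", 7, sex = "female",
#'                  life_stage = "adult")
#' abundance_record("ev1", "Ixodes", 40, life_stage = "larvae")
#' @export
abundance_record <- function(event_ref, name, value, unit = "individuals",
                             sex = "unknown", life_stage = "unknown",
                             rank = NULL, sample_name = NA_character_) {
  value <- as.numeric(value)
  if (is.na(value) || value < 0) {
    abort("invariant violated: value must be a non-negative number",
          class = "miread_invariant")
  }
  if (is.null(rank)) {
    ta <- resolve_rank(strsplit(stringr::str_squish(name), " ")[[1]])
    rank <- ta$rank
    name <- ta$name
  }
  tibble(
    event_ref = as.character(event_ref),
    rank = as.character(rank), name = as.character(name),
    sex = normalize_sex(sex), life_stage = normalize_life_stage(life_stage),
    value = value, unit = as.character(unit),
    sample_name = as.character(sample_name)
  )
}

#' Assemble a MIReAD dataset
#'
#' Bundles resource metadata, sampling events and abundance records into
#' the unit on which validation, normalization and export operate.
#' Structural invariants — unique `sample_id`s and every record's
#' `event_ref` resolving to exactly one event — are enforced here;
#' content-level problems (bad coordinates, ambiguous dates, duplicate
#' record keys, ...) are deliberately representable so that
#' [validate_dataset()] can report them as findings.
#'
#' @param metadata A [miread_metadata()] object.
#' @param events Events tibble (rows from [sampling_event()] or built by
#'   ingestion).
#' @param records Records tibble (rows from [abundance_record()]).
#' @param layout `"long"` or `"wide"` — the layout of the source the
#'   dataset was read from (generated datasets are long).
#' @param raw Optional retained [read_table()] result, used by
#'   structure-level validation rules.
#' @param ingest_findings Findings tibble carried over from ingestion.
#' @return An object of class `miread_dataset`.
#' @export
miread_dataset <- function(metadata = miread_metadata(),
                           events = empty_events(),
                           records = empty_records(),
                           layout = "long",
                           raw = NULL,
                           ingest_findings = empty_findings()) {
  stopifnot(inherits(metadata, "miread_metadata"))
  events <- as_tibble(events)
  records <- as_tibble(records)
  if (anyDuplicated(events$sample_id)) {
    abort("invariant violated: sample_id values must be unique within a dataset",
          class = "miread_invariant")
  }
  unresolved <- setdiff(records$event_ref, events$sample_id)
  if (length(unresolved)) {
    abort(paste0("invariant violated: event_ref does not resolve to an event: ",
                 paste(unresolved, collapse = ", ")),
          class = "miread_invariant")
  }
  structure(
    list(metadata = metadata, events = events, records = records,
         layout = layout, raw = raw, ingest_findings = ingest_findings),
    class = "miread_dataset"
  )
}

#' @export
print.miread_dataset <- function(x, ...) {
  cat(sprintf("<miread_dataset> %d events, %d records (%s layout)\n",
              nrow(x$events), nrow(x$records), x$layout))
  if (nrow(x$records)) {
    taxa <- sort(unique(x$records$name))
    cat("  taxa:", paste(utils::head(taxa, 5), collapse = ", "),
        if (length(taxa) > 5) sprintf("... (%d total)", length(taxa)) else "",
        "\n")
    cat(sprintf("  dates: %s to %s\n",
                min(x$events$start_date, na.rm = TRUE),
                max(x$events$end_date, na.rm = TRUE)))
  }
  invisible(x)
}

#' Read and write resource metadata files
#'
#' Resource metadata travels alongside the data table as a small YAML (or
#' JSON) document whose keys mirror the arguments of [miread_metadata()].
#' The conventional sidecar name for `data.csv` is
#' `data.csv.metadata.yml`, which the command-line tool discovers
#' automatically.
#'
#' @param path Path to a `.yml`/`.yaml`/`.json` metadata document.
#' @return A [miread_metadata()] object.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("metadata file not found: ", path), class = "miread_io")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(miread_metadata))
  cfg <- cfg[intersect(names(cfg), known)]
  do.call(miread_metadata, cfg)
}

#' @rdname read_metadata
#' @param meta A [miread_metadata()] to serialize.
#' @return For `write_metadata()`: `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "miread_metadata"))
  yaml::write_yaml(unclass(meta), path)
  invisible(path)
}

#' Resolve taxonomic rank from name tokens
#'
#' The most precise rank asserted is inferred from the number of tokens in
#' the scientific name: one token is a genus-level assignment (the common
#' case for larvae that cannot be keyed further), two a species binomial,
#' three a subspecies trinomial. The resolver never invents a species
#' epithet, and rejects unexpanded abbreviations (`"A. aegypti"`): the
#' no-abbreviations rule makes a single-letter genus unrecoverable.
#'
#' @param name_parts Character vector of name tokens.
#' @param sex,life_stage Optional labels attached to the assignment.
#' @return A one-row tibble with `rank`, `name`, `sex`, `life_stage`.
#' @examples
#' resolve_rank(c("Ixodes"))
#' resolve_rank(c("Aedes", "aegypti"))
#' @export
resolve_rank <- function(name_parts, sex = "unknown", life_stage = "unknown") {
  name_parts <- as.character(name_parts)
  name_parts <- name_parts[nzchar(stringr::str_squish(name_parts))]
  if (!length(name_parts)) {
    abort("empty taxonomic name", class = "miread_empty_name")
  }
  abbrev <- grepl("^[A-Za-z]\\.$", name_parts)
  if (any(abbrev)) {
    abort(paste0("abbreviated name token not allowed: ",
                 name_parts[abbrev][1]),
          class = "miread_abbreviation")
  }
  rank <- switch(as.character(min(length(name_parts), 3)),
                 "1" = "genus", "2" = "species", "3" = "subspecies")
  tibble(rank = rank, name = paste(name_parts, collapse = " "),
         sex = normalize_sex(sex), life_stage = normalize_life_stage(life_stage))
}

#' Canonical record key
#'
#' The deterministic identity of an abundance record for duplicate
#' detection and layout round-trips: `(event_ref, rank, name, sex,
#' life_stage, unit)`, with the name case-folded and enums in canonical
#' form. The value is deliberately excluded — two records that differ only
#' in value are duplicates of one cell, which is a validation error, not
#' two observations.
#'
#' @param records A records tibble (or one-row record).
#' @return Character vector of keys, one per record row.
#' @export
canonical_key <- function(records) {
  paste(records$event_ref,
        records$rank,
        tolower(stringr::str_squish(records$name)),
        normalize_sex(records$sex),
        normalize_life_stage(records$life_stage),
        tolower(stringr::str_squish(records$unit)),
        sep = "\x1f")
}
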