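# Field routings to the GBIF metadata profile and to Darwin Core. The
# event-centric half of the standard (when/where/how) becomes the DwC
# event core; observed quantities become occurrence-extension rows keyed
# on eventID. These tables are the single source of truth: the mappers
# implement them and an introspection test asserts coverage.

DWC <- "http://rs.tdwg.org/dwc/terms/"

#' Field routing tables
#'
#' The documented routings from the standard's concepts to the GBIF
#' metadata profile (resource metadata, 7 routings) and to Darwin Core
#' (data fields, 12 routings). [map_metadata()], [map_event()] and
#' [map_occurrence()] implement exactly these routings.
#'
#' @return A list of two tibbles, `metadata` (`miread_field`,
#'   `gbif_field`) and `data` (`miread_field`, `dwc_field`).
#' @export
dwc_field_routing <- function() {
  list(
    metadata = tibble(
      miread_field = c("contact", "study_description", "citations",
                       "identification_method", "absence_policy",
                       "gps_obfuscation", "usage_rights"),
      gbif_field = c("contact", "designDescription", "citation",
                     "designDescription", "samplingDescription",
                     "geographicDescription; geodeticDatum",
                     "intellectualRights")
    ),
    data = tibble(
      miread_field = c("start_time", "end_time", "location",
                       "collection_method", "attractants",
                       "collection_area", "taxonomy", "unit", "value",
                       "additional_info", "sample_id", "sample_name"),
      dwc_field = c("eventDate; eventTime", "eventDate; eventTime",
                    "decimalLatitude; decimalLongitude; locality; geodeticDatum",
                    "samplingProtocol", "samplingProtocol",
                    "samplingEffort",
                    "scientificName; taxonRank; genus; specificEpithet; infraspecificEpithet",
                    "sampleSizeUnit", "sampleSizeValue",
                    "fieldNotes; eventRemarks", "eventID", "fieldNumber")
    )
  )
}

#' Map resource metadata to the GBIF metadata profile
#'
#' Routes each non-empty resource-metadata field to its GBIF profile
#' target: the study description and the species identification method
#' both land in `designDescription` (as labelled subsections), the
#' absence policy in `samplingDescription`, GPS obfuscation in
#' `geographicDescription` plus `geodeticDatum`, usage rights in
#' `intellectualRights`, citations in `citation`. Empty source fields
#' produce no output element.
#'
#' @param meta A [miread_metadata()].
#' @return A named list of class `gbif_metadata`; empty fields omitted.
#' @export
map_metadata <- function(meta) {
  stopifnot(inherits(meta, "miread_metadata"))
  out <- list()
  if (nzchar(meta$contact)) out$contact <- meta$contact
  design <- c(
    if (nzchar(meta$study_description)) {
      paste0("Study design: ", meta$study_description)
    },
    if (nzchar(meta$identification_method)) {
      paste0("Species identification method: ", meta$identification_method)
    })
  if (length(design)) out$designDescription <- paste(design, collapse = " | ")
  sampling <- c(
    paste0("Absence interpretation: ", absence_policy_text(meta)),
    if (nzchar(meta$absence_note)) meta$absence_note)
  if (nzchar(meta$absence_policy)) {
    out$samplingDescription <- paste(sampling, collapse = " | ")
  }
  if (length(meta$citations) && any(nzchar(meta$citations))) {
    out$citation <- meta$citations[nzchar(meta$citations)]
  }
  if (nzchar(meta$gps_obfuscation)) {
    out$geographicDescription <- meta$gps_obfuscation
  }
  out$geodeticDatum <- if (nzchar(meta$datum)) meta$datum else "WGS84"
  if (nzchar(meta$usage_rights)) out$intellectualRights <- meta$usage_rights
  structure(out, class = "gbif_metadata")
}

absence_policy_text <- function(meta) {
  switch(meta$absence_policy,
         explicit_zeros = "zero counts are reported explicitly",
         absent_means_unknown = "a taxon absent from the table was not assessed (unknown)",
         absent_means_zero = "a taxon absent from the table was looked for and not found (zero)",
         meta$absence_policy)
}

#' Map sampling events to Darwin Core event-core rows
#'
#' `sample_id` becomes `eventID`; start/end dates become `eventDate` (a
#' single date when equal, an ISO 8601 `start/end` interval otherwise);
#' clock times go to `eventTime` (interval when both present); method and
#' attractants are combined into `samplingProtocol` (attractants appended
#' as `"attractant: ..."`); effort/area goes to `samplingEffort`; and
#' each `additional_info` attribute is serialized as `"key: value"` into
#' both `fieldNotes` and `eventRemarks` (the routing names both targets
#' without a split criterion, so they are emitted identically).
#'
#' @param events An events tibble.
#' @param datum Geodetic datum label (from the metadata; defaults WGS84).
#' @return A tibble of Darwin Core event rows.
#' @export
map_event <- function(events, datum = "WGS84") {
  if (any(is.na(events$start_date))) {
    abort(paste0("event without a usable date cannot be mapped: ",
                 paste(events$sample_id[is.na(events$start_date)],
                       collapse = ", ")),
          class = "miread_unmappable_event")
  }
  start <- format(events$start_date, "%Y-%m-%d")
  end <- ifelse(is.na(events$end_date), start,
                format(events$end_date, "%Y-%m-%d"))
  event_date <- ifelse(end == start, start, paste0(start, "/", end))
  sc <- events$start_clock
  ec <- events$end_clock
  event_time <- dplyr::case_when(
    !is.na(sc) & !is.na(ec) ~ paste0(sc, "/", ec),
    !is.na(sc) ~ sc,
    !is.na(ec) ~ ec,
    TRUE ~ NA_character_
  )
  protocol <- ifelse(
    is.na(events$attractants) | !nzchar(events$attractants),
    events$collection_method,
    paste0(events$collection_method, "; attractant: ", events$attractants))
  remarks <- vapply(events$additional_info, function(ai) {
    ai <- ai[!is.na(ai) & nzchar(ai)]
    if (!length(ai)) NA_character_
    else paste(paste0(names(ai), ": ", unname(ai)), collapse = "; ")
  }, character(1))
  tibble(
    eventID = events$sample_id,
    eventDate = event_date,
    eventTime = event_time,
    decimalLatitude = events$latitude,
    decimalLongitude = events$longitude,
    geodeticDatum = datum,
    locality = events$locality_text,
    samplingProtocol = protocol,
    samplingEffort = events$collection_area,
    fieldNotes = remarks,
    eventRemarks = remarks
  )
}

#' Map abundance records to Darwin Core occurrence rows
#'
#' Rank-appropriate taxon fields are set from the record's assignment: a
#' genus-only record (larvae that cannot be keyed further) sets `genus`
#' and `scientificName` to the genus with no species epithet; binomials
#' and trinomials fill `specificEpithet`/`infraspecificEpithet`. The
#' value and unit go to `sampleSizeValue`/`sampleSizeUnit` and are
#' duplicated into `organismQuantity`/`organismQuantityType` for
#' aggregator friendliness; `occurrenceStatus` is `"absent"` exactly when
#' the value is 0. `occurrenceID` is `eventID:ordinal` with ordinals
#' assigned deterministically in record order within each event.
#'
#' @param records A records tibble (canonical).
#' @return A tibble of Darwin Core occurrence rows.
#' @export
map_occurrence <- function(records) {
  toks <- strsplit(records$name, " ")
  genus <- vapply(toks, function(t) t[1] %||% NA_character_, character(1))
  specific <- vapply(toks, function(t)
    if (length(t) >= 2) t[2] else "", character(1))
  infra <- vapply(toks, function(t)
    if (length(t) >= 3) t[3] else "", character(1))
  ord <- stats::ave(seq_len(nrow(records)), records$event_ref,
                    FUN = seq_along)
  tibble(
    occurrenceID = paste0(records$event_ref, ":", ord),
    eventID = records$event_ref,
    scientificName = records$name,
    taxonRank = records$rank,
    genus = genus,
    specificEpithet = specific,
    infraspecificEpithet = infra,
    sex = records$sex,
    lifeStage = records$life_stage,
    sampleSizeValue = records$value,
    sampleSizeUnit = records$unit,
    organismQuantity = records$value,
    organismQuantityType = records$unit,
    occurrenceStatus = ifelse(records$value == 0, "absent", "present"),
    fieldNumber = records$sample_name
  )
}

dwc_table_text <- function(tab) {
  fmt <- vapply(seq_len(nrow(tab)), function(i) {
    cells <- vapply(seq_along(tab), function(j) {
      v <- tab[[j]][i]
      if (is.numeric(v)) {
        if (is.na(v)) "" else format_value(v)
      } else if (is.na(v)) "" else as.character(v)
    }, character(1))
    paste(cells, collapse = "\t")
  }, character(1))
  paste0(paste(c(paste(names(tab), collapse = "\t"), fmt),
               collapse = "\n"), "\n")
}

meta_xml_text <- function(event_cols, occ_cols) {
  doc <- xml2::xml_new_root("archive",
                            xmlns = "http://rs.tdwg.org/dwc/text/",
                            metadata = "eml.xml")
  core <- xml2::xml_add_child(
    doc, "core", encoding = "UTF-8", fieldsTerminatedBy = "\\t",
    linesTerminatedBy = "\\n", fieldsEnclosedBy = "",
    ignoreHeaderLines = "1",
    rowType = paste0(DWC, "Event"))
  files <- xml2::xml_add_child(core, "files")
  xml2::xml_add_child(files, "location", "event.txt")
  xml2::xml_add_child(core, "id", index = "0")
  for (i in seq_along(event_cols)) {
    xml2::xml_add_child(core, "field", index = as.character(i - 1),
                        term = paste0(DWC, event_cols[i]))
  }
  ext <- xml2::xml_add_child(
    doc, "extension", encoding = "UTF-8", fieldsTerminatedBy = "\\t",
    linesTerminatedBy = "\\n", fieldsEnclosedBy = "",
    ignoreHeaderLines = "1",
    rowType = paste0(DWC, "Occurrence"))
  files <- xml2::xml_add_child(ext, "files")
  xml2::xml_add_child(files, "location", "occurrence.txt")
  xml2::xml_add_child(ext, "coreid", index = "1")
  for (i in seq_along(occ_cols)) {
    xml2::xml_add_child(ext, "field", index = as.character(i - 1),
                        term = paste0(DWC, occ_cols[i]))
  }
  as.character(doc)
}

#' Standalone EML export
#'
#' Serializes the GBIF-profile metadata as an EML document: contact,
#' design and sampling descriptions, geographic description with the
#' geodetic datum, intellectual rights, citations.
#'
#' @param meta A [miread_metadata()] or [map_metadata()] result.
#' @param path Optional output path.
#' @return The EML XML as a string; invisibly when written to `path`.
#' @export
write_eml <- function(meta, path = NULL) {
  gbif <- if (inherits(meta, "gbif_metadata")) meta else map_metadata(meta)
  doc <- xml2::xml_new_root(
    "eml:eml",
    "xmlns:eml" = "https://eml.ecoinformatics.org/eml-2.2.0",
    packageId = "miread-dataset", system = "miread")
  ds <- xml2::xml_add_child(doc, "dataset")
  xml2::xml_add_child(ds, "title", "Arthropod abundance dataset")
  if (!is.null(gbif$contact)) {
    ct <- xml2::xml_add_child(ds, "contact")
    xml2::xml_add_child(ct, "organizationName", gbif$contact)
  }
  if (!is.null(gbif$intellectualRights)) {
    ir <- xml2::xml_add_child(ds, "intellectualRights")
    xml2::xml_add_child(ir, "para", gbif$intellectualRights)
  }
  cov <- xml2::xml_add_child(ds, "coverage")
  geo <- xml2::xml_add_child(cov, "geographicCoverage")
  geo_desc <- paste(
    c(gbif$geographicDescription,
      paste0("geodetic datum: ", gbif$geodeticDatum)), collapse = " | ")
  xml2::xml_add_child(geo, "geographicDescription", geo_desc)
  meth <- xml2::xml_add_child(ds, "methods")
  if (!is.null(gbif$designDescription)) {
    step <- xml2::xml_add_child(meth, "methodStep")
    dd <- xml2::xml_add_child(step, "description")
    xml2::xml_add_child(dd, "para", gbif$designDescription)
  }
  if (!is.null(gbif$samplingDescription)) {
    smp <- xml2::xml_add_child(meth, "sampling")
    sd <- xml2::xml_add_child(smp, "samplingDescription")
    xml2::xml_add_child(sd, "para", gbif$samplingDescription)
  }
  if (!is.null(gbif$citation)) {
    am <- xml2::xml_add_child(doc, "additionalMetadata")
    md <- xml2::xml_add_child(am, "metadata")
    bib <- xml2::xml_add_child(md, "bibliography")
    for (ci in gbif$citation) xml2::xml_add_child(bib, "citation", ci)
  }
  txt <- as.character(doc)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Write a Darwin Core Archive
#'
#' Exports a canonical dataset as a Darwin Core Archive: a zip holding
#' `event.txt` (event core), `occurrence.txt` (occurrence extension keyed
#' on `eventID`), `meta.xml` (column declarations by index and term URI)
#' and `eml.xml` (the GBIF-profile resource metadata). Files are UTF-8,
#' tab-delimited, Unix newlines; the archive is byte-stable for a fixed
#' dataset. The event core was chosen over an occurrence core because the
#' standard is sampling-event-centric: quantities are tied to documented
#' collection acts, which is what makes explicit zeros meaningful.
#'
#' @param dataset A [miread_dataset()].
#' @param path Output `.zip` path.
#' @param force Write even when validation reports errors.
#' @return `path`, invisibly.
#' @export
write_dwca <- function(dataset, path, force = FALSE) {
  report <- validate_dataset(dataset)
  if (!report$is_compliant && !force) {
    abort(paste0("dataset is not compliant (",
                 sum(report$findings$severity == "error"),
                 " error(s)); fix findings or use force = TRUE"),
          class = "miread_not_compliant")
  }
  dataset <- wide_to_long(dataset)
  events <- map_event(dataset$events, datum = dataset$metadata$datum)
  occurrences <- map_occurrence(dataset$records)
  entries <- list(
    "event.txt" = charToRaw(dwc_table_text(events)),
    "occurrence.txt" = charToRaw(dwc_table_text(occurrences)),
    "meta.xml" = charToRaw(paste0(
      meta_xml_text(names(events), names(occurrences)), "\n")),
    "eml.xml" = charToRaw(paste0(write_eml(dataset$metadata), "\n"))
  )
  write_zip(entries, path)
  invisible(path)
}
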