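test_that("resource metadata routes to the GBIF profile fields", {
  meta <- miread_metadata(
    contact = "J. Doe, j.doe@x.org",
    study_description = "Weekly light trapping",
    citations = c("Doe 2017"),
    identification_method = "morphological keys",
    absence_policy = "explicit_zeros",
    gps_obfuscation = "rounded to 0.1 degree",
    usage_rights = "CC-BY 4.0")
  g <- map_metadata(meta)
  expect_equal(g$contact, "J. Doe, j.doe@x.org")
  expect_match(g$designDescription, "Weekly light trapping")
  expect_match(g$designDescription, "morphological keys")
  expect_match(g$samplingDescription, "zero counts are reported explicitly")
  expect_equal(g$geographicDescription, "rounded to 0.1 degree")
  expect_equal(g$geodeticDatum, "WGS84")
  expect_equal(g$intellectualRights, "CC-BY 4.0")
  expect_equal(g$citation, "Doe 2017")
  # empty citations produce no element at all
  meta2 <- miread_metadata(contact = "x")
  expect_false("citation" %in% names(map_metadata(meta2)))
})

test_that("events map to ISO 8601 intervals and combined protocols", {
  ev <- sampling_event("E1", "2017-06-04", end_date = "2017-06-05",
                       start_clock = "18:00", end_clock = "06:00",
                       latitude = 41.66, longitude = -91.53,
                       collection_method = "New Jersey light trap",
                       attractants = "light",
                       collection_area = "1 trap-night",
                       additional_info = c("sub-location" = "cattle shed"))
  d <- map_event(ev)
  # oracle: the interval must split back into the original endpoints
  expect_equal(strsplit(d$eventDate, "/")[[1]],
               c("2017-06-04", "2017-06-05"))
  expect_equal(strsplit(d$eventTime, "/")[[1]], c("18:00", "06:00"))
  expect_equal(d$samplingProtocol, "New Jersey light trap; attractant: light")
  expect_equal(d$samplingEffort, "1 trap-night")
  expect_match(d$eventRemarks, "sub-location: cattle shed")
  expect_identical(d$fieldNotes, d$eventRemarks)
  # same-day sampling collapses to a single date
  same <- map_event(sampling_event("E2", "2017-06-04",
                                   collection_method = "drag"))
  expect_equal(same$eventDate, "2017-06-04")
  expect_true(is.na(same$eventTime))
  # an event with no date cannot be mapped
  ev_bad <- ev; ev_bad$start_date <- as.Date(NA)
  expect_error(map_event(ev_bad), class = "miread_unmappable_event")
})

test_that("occurrences carry rank-appropriate taxon fields and zero semantics", {
  rec <- dplyr::bind_rows(
    abundance_record("E1", "Ixodes", 40, life_stage = "larva"),
    abundance_record("E1", "Ixodes scapularis", 0, life_stage = "adult"),
    abundance_record("E2", "Aedes aegypti", 7, sex = "female"))
  occ <- map_occurrence(rec)
  expect_equal(occ$occurrenceID, c("E1:1", "E1:2", "E2:1"))
  expect_equal(occ$genus, c("Ixodes", "Ixodes", "Aedes"))
  expect_equal(occ$scientificName[1], "Ixodes")
  expect_equal(occ$specificEpithet, c("", "scapularis", "aegypti"))
  expect_equal(occ$lifeStage[1], "larva")
  expect_equal(occ$sampleSizeValue, c(40, 0, 7))
  expect_equal(occ$occurrenceStatus, c("present", "absent", "present"))
  expect_equal(occ$organismQuantity, occ$sampleSizeValue)
})

test_that("every documented routing is implemented exactly once", {
  routing <- dwc_field_routing()
  expect_equal(nrow(routing$metadata), 7)
  expect_equal(nrow(routing$data), 12)
  expect_false(anyDuplicated(routing$metadata$miread_field) > 0)
  expect_false(anyDuplicated(routing$data$miread_field) > 0)

  # each routed target is realized by the mappers (on fully-populated
  # metadata: empty optional fields are legitimately omitted)
  full_meta <- miread_metadata(
    contact = "J. Doe, j.doe@x.org", study_description = "trapping study",
    citations = "Doe 2017", identification_method = "keys",
    absence_policy = "explicit_zeros",
    gps_obfuscation = "rounded to 0.1 degree", usage_rights = "CC0")
  gbif_targets <- unique(unlist(strsplit(routing$metadata$gbif_field, "; ")))
  realized <- names(map_metadata(full_meta))
  expect_true(all(gbif_targets %in% realized))

  ds <- clean_ds("wide_subloc", seed = 1, n_events = 3)
  dwc_cols <- c(names(map_event(ds$events)),
                names(map_occurrence(ds$records)),
                "eventDate")
  dwc_targets <- unique(unlist(strsplit(routing$data$dwc_field, "; ")))
  expect_true(all(dwc_targets %in% dwc_cols))
})

test_that("archives hold consistent cores, extensions and declarations", {
  ds <- clean_ds("long_trap", seed = 1, n_events = 5, n_taxa = 3)
  z <- withr::local_tempfile(fileext = ".zip")
  write_dwca(ds, z)
  dir <- withr::local_tempdir()
  utils::unzip(z, exdir = dir)
  expect_setequal(list.files(dir),
                  c("event.txt", "occurrence.txt", "meta.xml", "eml.xml"))
  ev <- utils::read.delim(file.path(dir, "event.txt"), sep = "\t")
  oc <- utils::read.delim(file.path(dir, "occurrence.txt"), sep = "\t")
  expect_equal(nrow(ev), nrow(ds$events))
  expect_equal(nrow(oc), nrow(ds$records))
  expect_true(all(oc$eventID %in% ev$eventID))

  # meta.xml declarations agree with the emitted files, index by index
  meta <- xml2::read_xml(file.path(dir, "meta.xml"))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(meta), d1 = "dwca")
  core_fields <- xml2::xml_find_all(meta, ".//dwca:core/dwca:field", ns)
  terms <- basename(xml2::xml_attr(core_fields, "term"))
  idx <- as.integer(xml2::xml_attr(core_fields, "index"))
  expect_equal(terms[order(idx)], names(ev))
  ext_fields <- xml2::xml_find_all(meta, ".//dwca:extension/dwca:field", ns)
  eterms <- basename(xml2::xml_attr(ext_fields, "term"))
  eidx <- as.integer(xml2::xml_attr(ext_fields, "index"))
  expect_equal(eterms[order(eidx)], names(oc))

  # eml carries the resource metadata
  eml <- xml2::read_xml(file.path(dir, "eml.xml"))
  expect_match(as.character(eml), "Field Entomology Unit")
})

test_that("identical datasets produce byte-identical archives", {
  ds <- clean_ds(seed = 13)
  z1 <- withr::local_tempfile(fileext = ".zip")
  z2 <- withr::local_tempfile(fileext = ".zip")
  write_dwca(ds, z1)
  write_dwca(ds, z2)
  expect_identical(readBin(z1, "raw", file.size(z1)),
                   readBin(z2, "raw", file.size(z2)))
})

test_that("non-compliant datasets are refused unless forced", {
  bad <- corrupt_dataset(clean_ds(seed = 3), "D3_BAD_COORD", seed = 1)$dataset
  z <- withr::local_tempfile(fileext = ".zip")
  expect_error(write_dwca(bad, z), class = "miread_not_compliant")
  write_dwca(bad, z, force = TRUE)
  expect_true(file.exists(z))
})

test_that("an empty dataset still yields a valid archive shell", {
  ds <- miread_dataset(clean_ds()$metadata)
  z <- withr::local_tempfile(fileext = ".zip")
  write_dwca(ds, z)
  dir <- withr::local_tempdir()
  utils::unzip(z, exdir = dir)
  ev <- utils::read.delim(file.path(dir, "event.txt"), sep = "\t")
  expect_equal(nrow(ev), 0)
  expect_true(file.exists(file.path(dir, "eml.xml")))
})
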