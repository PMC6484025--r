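test_that("rank resolution follows token count and never invents epithets", {
  expect_equal(resolve_rank("Ixodes")$rank, "genus")
  expect_equal(resolve_rank("Ixodes")$name, "Ixodes")
  two <- resolve_rank(c("Aedes", "aegypti"))
  expect_equal(two$rank, "species")
  expect_equal(two$name, "Aedes aegypti")
  expect_equal(resolve_rank(c("Culex", "pipiens", "pipiens"))$rank,
               "subspecies")
  expect_error(resolve_rank(c("A.", "aegypti")),
               class = "miread_abbreviation")
  expect_error(resolve_rank(c("", "  ")), class = "miread_empty_name")
})

test_that("canonical keys identify cells, not values", {
  a <- abundance_record("E1", "Aedes aegypti", 7, sex = "female",
                        life_stage = "adult")
  b <- abundance_record("E1", "Aedes aegypti", 12, sex = "female",
                        life_stage = "adult")
  expect_identical(canonical_key(a), canonical_key(b))
  # per-stage records are distinct cells
  nymph <- abundance_record("E1", "Aedes aegypti", 7, sex = "female",
                            life_stage = "nymph")
  expect_false(canonical_key(a) == canonical_key(nymph))
  # pure: same input, same key, and case/spacing folded
  a2 <- abundance_record("E1", "AEDES AEGYPTI", 7, sex = "F",
                         life_stage = "adults", rank = "species")
  expect_identical(canonical_key(a), canonical_key(a2))
  expect_identical(canonical_key(a), canonical_key(a))
})

test_that("constructors reject invariant violations and name them", {
  expect_error(sampling_event("e", "2017-06-04", latitude = 95),
               "latitude", class = "miread_invariant")
  expect_error(sampling_event("e", "2017-06-04", longitude = -200),
               "longitude", class = "miread_invariant")
  expect_error(sampling_event("e", "2017-06-05", end_date = "2017-06-04"),
               "start_time", class = "miread_invariant")
  # equal start and end is legal: cross-sectional sampling
  ev <- sampling_event("e", "2017-06-04", end_date = "2017-06-04")
  expect_equal(ev$start_date, ev$end_date)
  expect_error(abundance_record("e", "Aedes aegypti", -1),
               "non-negative", class = "miread_invariant")
})

test_that("dataset assembly enforces referential structure", {
  ev <- dplyr::bind_rows(
    sampling_event("E1", "2017-06-04", latitude = 40, longitude = -90,
                   collection_method = "light trap"),
    sampling_event("E2", "2017-06-05", latitude = 40, longitude = -90,
                   collection_method = "light trap"))
  rec <- abundance_record("E1", "Aedes aegypti", 3)
  ds <- miread_dataset(miread_metadata(), ev, rec)
  expect_s3_class(ds, "miread_dataset")

  dup <- dplyr::bind_rows(ev, ev[1, ])
  expect_error(miread_dataset(miread_metadata(), dup, rec),
               "sample_id", class = "miread_invariant")
  orphan <- abundance_record("E9", "Aedes aegypti", 3)
  expect_error(miread_dataset(miread_metadata(), ev, orphan),
               "event_ref", class = "miread_invariant")
})

test_that("sex and life-stage labels normalize case-insensitively", {
  expect_equal(normalize_sex(c("F", "Females", "♀", "junk", NA)),
               c("female", "female", "female", "unknown", "unknown"))
  expect_equal(normalize_life_stage(c("Larvae", "NYMPHS", "imago")),
               c("larva", "nymph", "adult"))
  # mapping-config synonyms extend the built-ins
  expect_equal(normalize_sex("hembra", synonyms = c(hembra = "female")),
               "female")
})

test_that("metadata reads and writes through its YAML sidecar form", {
  meta <- miread_metadata(contact = "A. Person, a@example.org",
                          study_description = "CO2-baited trapping",
                          identification_method = "keys",
                          absence_policy = "explicit_zeros",
                          usage_rights = "CC0")
  path <- withr::local_tempfile(fileext = ".yml")
  write_metadata(meta, path)
  back <- read_metadata(path)
  expect_identical(unclass(back), unclass(meta))
})
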