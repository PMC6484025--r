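test_that("pivoting wide keeps zeros and conserves totals", {
  lines <- c(paste0("date,latitude,longitude,method,",
                    '"Aedes aegypti (individuals)","Culex pipiens (individuals)"'),
             "2017-06-04,41.66,-91.53,light trap,7,0")
  p <- write_lines_csv(lines)
  ds <- bind_columns(read_table(p), metadata = miread_metadata(
    absence_policy = "explicit_zeros"))
  canon <- wide_to_long(ds)
  expect_equal(canon$layout, "long")
  expect_equal(sort(canon$records$value), c(0, 7))
  expect_equal(sum(canon$records$value), 7)
})

test_that("layout round-trips preserve the canonical record multiset", {
  for (seed in c(1, 7)) {
    ds <- clean_ds("tick_drag", seed = seed, n_events = 5)
    wide <- long_to_wide(ds)
    # two life stages of one species occupy two distinct columns
    stage_cols <- grep("Ixodes scapularis", names(wide), value = TRUE)
    expect_length(stage_cols, 2)
    expect_true(any(grepl("larva", names(wide))))

    p <- withr::local_tempfile(fileext = ".csv")
    write_wide_csv(ds, p)
    back <- wide_to_long(bind_columns(read_table(p), metadata = ds$metadata))
    expect_identical(record_multiset(back$records),
                     record_multiset(ds$records))
    expect_equal(sum(back$records$value), sum(ds$records$value))
  }
})

test_that("normalizing a canonical dataset is a no-op", {
  ds <- clean_ds(seed = 2)
  again <- wide_to_long(wide_to_long(ds))
  expect_identical(again$records, ds$records)
  expect_identical(again$events, ds$events)
})

test_that("an empty dataset pivots to a header-only table", {
  ds <- miread_dataset(miread_metadata())
  wide <- long_to_wide(ds)
  expect_equal(nrow(wide), 0)
  expect_true("sample_id" %in% names(wide))
})

test_that("colliding taxon columns are refused as duplicate keys", {
  ds <- clean_ds(seed = 4)
  ds$records <- dplyr::bind_rows(ds$records, ds$records[1, ])
  expect_error(long_to_wide(ds), class = "miread_duplicate_key")
})

test_that("composite counts split into linked per-class records", {
  ev <- sampling_event("D1", "2017-05-10", latitude = 42.1, longitude = -85.3,
                       collection_method = "tick drag", sample_name = "drag-1")
  composite <- abundance_record("D1", "Ixodes scapularis", 48,
                                life_stage = "mixed", sample_name = "drag-1")
  ds <- miread_dataset(miread_metadata(), ev, composite)
  counts <- tibble::tibble(
    event_ref = "D1",
    name = c("Ixodes scapularis", "Ixodes scapularis", "Ixodes"),
    life_stage = c("adult", "nymph", "larva"),
    value = c(3, 5, 40))
  split <- split_linked_records(ds, counts)
  expect_equal(nrow(split$records), 3)
  expect_equal(sum(split$records$value), 48)
  expect_equal(unique(split$records$sample_name), "drag-1")
  # the larval split drops to genus rank
  larva <- dplyr::filter(split$records, .data$life_stage == "larva")
  expect_equal(larva$rank, "genus")
  expect_equal(larva$name, "Ixodes")
  # idempotent on already-split data
  again <- split_linked_records(split, counts)
  expect_identical(record_multiset(again$records),
                   record_multiset(split$records))
})

test_that("unsplittable composites stay whole with a warning", {
  ev <- sampling_event("D1", "2017-05-10", latitude = 42.1, longitude = -85.3,
                       collection_method = "host search")
  composite <- abundance_record("D1", "Aedes aegypti", 12, sex = "mixed")
  ds <- miread_dataset(miread_metadata(), ev, composite)
  out <- split_linked_records(ds, tibble::tibble(
    event_ref = "D9", name = "Aedes aegypti", sex = "female", value = 12))
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$sex, "mixed")
  expect_match(attr(out, "split_warnings"), "kept composite")
})

test_that("host descriptors live on the event, not the arthropod", {
  ds <- clean_ds("host_ectoparasite", seed = 6, n_events = 4)
  info <- ds$events$additional_info
  expect_true(all(vapply(info, function(ai) "host sex" %in% names(ai),
                         logical(1))))
  expect_true(all(ds$records$sex == "unknown"))  # parasite sex unasserted
  # explicit attachment
  plain <- clean_ds(seed = 6, n_events = 2)
  out <- attach_host_context(plain, stats::setNames("female",
                                                    plain$events$sample_id[1]))
  expect_equal(out$events$additional_info[[1]][["host sex"]], "female")
  expect_identical(attach_host_context(plain)$events, plain$events)
})

test_that("the canonical CSV round-trips datasets exactly", {
  ds <- clean_ds("wide_subloc", seed = 8, n_events = 5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_canonical_csv(ds, p)
  back <- read_canonical_csv(p, metadata = ds$metadata)
  expect_identical(record_multiset(back$records), record_multiset(ds$records))
  expect_equal(back$events$start_clock, ds$events$start_clock)
  expect_equal(back$events$lat_raw, ds$events$lat_raw)
  expect_true(validate_dataset(back)$is_compliant)
})
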