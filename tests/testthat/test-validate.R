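test_that("clean generated datasets validate with zero findings", {
  rep <- validate_dataset(clean_ds("long_trap", seed = 11))
  expect_true(rep$is_compliant)
  expect_equal(nrow(rep$findings), 0)
})

test_that("blanking a required metadata field is a completeness error", {
  ds <- clean_ds()
  ds$metadata$identification_method <- ""
  rep <- validate_dataset(ds)
  expect_false(rep$is_compliant)
  hit <- dplyr::filter(rep$findings, .data$rule_id == "M3_IDENTIFICATION_METHOD")
  expect_equal(nrow(hit), 1)
  expect_match(hit$message, "Species Identification Method")
})

test_that("injected fault sets surface as exactly those error classes", {
  out <- corrupt_dataset(clean_ds(seed = 3), c("R3_DATE", "D3_BAD_COORD"),
                         seed = 9)
  rep <- validate_dataset(out$dataset)
  errs <- unique(rep$findings$rule_id[rep$findings$severity == "error"])
  expect_setequal(errs, c("R3_DATE", "D3_BAD_COORD"))
})

test_that("abbreviation rule flags shorthand but exempts units and trap names", {
  ds <- clean_ds()
  ds$raw$header[match("collection_method", ds$raw$header)] <- "Col. Meth."
  rep <- validate_dataset(ds)
  hit <- dplyr::filter(rep$findings, .data$rule_id == "R1_ABBREV")
  expect_true(any(hit$column == "Col. Meth."))
  expect_true(all(hit$severity == "warning"))

  ds2 <- clean_ds()
  ds2$raw$header[1] <- "Temperature (°C)"   # unit annotation exempt
  ds2$events$collection_method <- "CDC light trap"  # lexicon exempt
  rep2 <- validate_dataset(ds2)
  expect_false("R1_ABBREV" %in% rep2$findings$rule_id)
})

test_that("opaque location and taxon codes need no external key file", {
  ds <- clean_ds()
  ds$events$latitude[2] <- NA; ds$events$longitude[2] <- NA
  ds$events$lat_raw[2] <- NA; ds$events$lon_raw[2] <- NA
  ds$events$locality_text[2] <- "site_07"
  rep <- validate_dataset(ds)
  hit <- dplyr::filter(rep$findings, .data$rule_id == "R2_EXTERNAL_KEY")
  expect_equal(hit$row, 2L)
  expect_true(all(hit$severity == "error"))

  # coordinates plus a site label are self-contained
  ds2 <- clean_ds()
  ds2$events$locality_text <- "site_07"
  expect_false("R2_EXTERNAL_KEY" %in% validate_dataset(ds2)$findings$rule_id)

  ds3 <- clean_ds()
  ds3$records$name[1] <- "sp3"
  expect_rule(validate_dataset(ds3), "R2_EXTERNAL_KEY")
})

test_that("heading rows and ditto-dependent rows violate line isolation", {
  ds <- clean_ds()
  ds$raw$rows <- append(ds$raw$rows, list(c("June collections",
                                            rep("", length(ds$raw$header) - 1))),
                        after = 2)
  rep <- validate_dataset(ds)
  hit <- dplyr::filter(rep$findings, .data$rule_id == "R5_STYLING")
  expect_equal(hit$row, 3L)
  expect_true(all(hit$severity == "error"))

  ds2 <- clean_ds()
  r <- ds2$raw$rows[[1]]
  r[match("start_date", ds2$raw$header)] <- ""
  ds2$raw$rows[[1]] <- r
  expect_rule(validate_dataset(ds2), "R5_STYLING")
})

test_that("coordinate precision interacts with declared obfuscation", {
  ds <- clean_ds()
  ds$events$lat_raw[1] <- "8.5"; ds$events$latitude[1] <- 8.5
  rep <- validate_dataset(ds)
  hit <- dplyr::filter(rep$findings, .data$rule_id == "R6_PRECISION")
  expect_equal(hit$severity, "warning")

  # a dataset uniformly rounded under a declared policy is fine
  obf <- clean_ds()
  obf$events$latitude <- round(obf$events$latitude, 1)
  obf$events$longitude <- round(obf$events$longitude, 1)
  obf$events$lat_raw <- sprintf("%.1f", obf$events$latitude)
  obf$events$lon_raw <- sprintf("%.1f", obf$events$longitude)
  obf$metadata$gps_obfuscation <-
    "coordinates rounded to 0.1 degree for landowner privacy"
  expect_false("R6_PRECISION" %in% validate_dataset(obf)$findings$rule_id)

  # a coordinate finer than the declaration contradicts it
  obf$events$lat_raw[2] <- "8.512345"; obf$events$latitude[2] <- 8.512345
  rep3 <- validate_dataset(obf)
  hit3 <- dplyr::filter(rep3$findings, .data$rule_id == "R6_PRECISION")
  expect_equal(hit3$row, 2L)
  expect_equal(hit3$severity, "error")
})

test_that("duplicate cells, relative units and impossible values are errors", {
  ds <- clean_ds()
  ds$records <- dplyr::bind_rows(ds$records, ds$records[1, ])
  expect_rule(validate_dataset(ds), "D1_DUPLICATE_KEY")

  ds2 <- clean_ds()
  ds2$records$unit[1] <- "relative abundance"
  expect_rule(validate_dataset(ds2), "D2_RELATIVE_ABUNDANCE")

  ds3 <- clean_ds()
  ds3$events$latitude[1] <- 95; ds3$events$lat_raw[1] <- "95.0000"
  expect_rule(validate_dataset(ds3), "D3_BAD_COORD")

  ds4 <- clean_ds()
  ds4$events$start_date[1] <- ds4$events$end_date[1] + 2
  expect_rule(validate_dataset(ds4), "D4_TIME_ORDER")
})

test_that("non-ASCII field names warn but never block", {
  ds <- clean_ds()
  ds$raw$header[1] <- "espèce"
  rep <- validate_dataset(ds)
  hit <- dplyr::filter(rep$findings, .data$rule_id == "R7_LANGUAGE")
  expect_equal(hit$column, "espèce")
  expect_true(rep$is_compliant)
})

test_that("reports are deterministic and ordered", {
  ds <- corrupt_dataset(clean_ds(seed = 5), "all", seed = 2)$dataset
  r1 <- report_json(validate_dataset(ds))
  r2 <- report_json(validate_dataset(ds))
  expect_identical(r1, r2)
  f <- validate_dataset(ds)$findings
  expect_identical(f, dplyr::arrange(f, .data$rule_id, .data$row,
                                     .data$column, .data$message))
})

test_that("report accessors summarise findings", {
  ds <- clean_ds()
  ds$metadata$contact <- ""
  rep <- validate_dataset(ds)
  expect_identical(tidy(rep), rep$findings)
  g <- glance(rep)
  expect_equal(g$n_errors, 1)
  expect_false(g$is_compliant)
  expect_s3_class(autoplot(rep), "ggplot")
})
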