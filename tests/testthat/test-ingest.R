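test_that("delimited tables parse with sniffed delimiters", {
  p <- write_lines_csv(c("date,species,count", "2017-06-04,Aedes aegypti,3"))
  raw <- read_table(p)
  expect_length(raw$header, 3)
  expect_length(raw$rows, 1)
  expect_equal(raw$dialect$delimiter, ",")

  p2 <- write_lines_csv(c("date;species;count", "2017-06-04;Aedes aegypti;3"))
  expect_equal(read_table(p2)$dialect$delimiter, ";")
  p3 <- write_lines_csv(c("date\tspecies\tcount", "2017-06-04\tAedes\t3"))
  expect_equal(read_table(p3)$dialect$delimiter, "\t")
  # quoted fields keep embedded delimiters
  p4 <- write_lines_csv(c('date,"taxon, annotated",count',
                          '2017-06-04,"Aedes aegypti, female",3'))
  expect_equal(read_table(p4)$rows[[1]][2], "Aedes aegypti, female")
})

test_that("non-machine-readable and malformed inputs are refused", {
  pdf <- withr::local_tempfile(fileext = ".pdf")
  writeLines("%PDF-1.4 fake", pdf)
  expect_error(read_table(pdf), class = "miread_not_machine_readable")

  ragged <- write_lines_csv(c("a,b,c", "1,2,3", "1,2,3,4"))
  expect_error(read_table(ragged), class = "miread_ragged")

  expect_error(read_table(file.path(tempdir(), "no-such-file.csv")),
               class = "miread_io")
})

test_that("a blank-row-delimited second block is a structure finding", {
  p <- write_lines_csv(c("date,species,count", "2017-06-04,Aedes aegypti,3",
                         "", "another,block,here"))
  raw <- read_table(p)
  expect_true("R5_STYLING" %in% raw$findings$rule_id)
})

test_that("layout detection distinguishes long, wide and ambiguous", {
  long <- write_lines_csv(c("date,location,species,count",
                            "2017-06-04,site A,Aedes aegypti,3"))
  expect_equal(detect_layout(read_table(long)), "long")

  wide <- write_lines_csv(c(
    paste0("date,sub-location,\"Aedes aegypti, female, adult (individuals)\",",
           "\"Culex pipiens, female, adult (individuals)\""),
    "2017-06-04,cattle shed,3,0"))
  expect_equal(detect_layout(read_table(wide)), "wide")

  amb <- write_lines_csv(c("date,notes", "2017-06-04,windy"))
  expect_error(detect_layout(read_table(amb)),
               class = "miread_ambiguous_layout")
})

test_that("binding builds one record per long row and flags unbound columns", {
  p <- write_lines_csv(c(
    "date,latitude,longitude,species,count,Temp (°C),method",
    "2017-06-04,41.6611,-91.5302,Aedes aegypti,3,21,light trap",
    "2017-06-04,41.6611,-91.5302,Culex pipiens,5,21,light trap",
    "2017-06-11,41.6611,-91.5302,Aedes aegypti,1,19,light trap"))
  ds <- bind_columns(read_table(p))
  expect_equal(nrow(ds$records), 3)
  expect_equal(nrow(ds$events), 2)  # two distinct event keys
  unbound <- dplyr::filter(ds$ingest_findings,
                           grepl("unbound", .data$message))
  expect_equal(unbound$column, "Temp (°C)")
  # the unbound cell is still reachable on the event
  expect_equal(ds$events$additional_info[[1]][["Temp (°C)"]], "21")
})

test_that("wide binding yields one record per non-empty cell", {
  # brute-force oracle: enumerate cells of the value matrix
  n <- 4; taxa <- c("Aedes aegypti", "Culex pipiens", "Culiseta melanura")
  set.seed(42)
  vals <- matrix(rpois(n * length(taxa), 5), nrow = n)
  header <- c("date,latitude,longitude,method",
              paste0('"', taxa, ', female, adult (individuals)"'))
  lines <- paste(header, collapse = ",")
  for (i in seq_len(n)) {
    lines <- c(lines, paste(c(sprintf("2017-06-%02d", i), "41.66", "-91.53",
                              "light trap", vals[i, ]), collapse = ","))
  }
  p <- write_lines_csv(lines)
  ds <- bind_columns(read_table(p))
  expect_equal(ds$layout, "wide")
  expect_equal(nrow(ds$records), n * length(taxa))
  expect_equal(sum(ds$records$value), sum(vals))
})

test_that("empty wide cells follow the declared absence policy", {
  lines <- c(paste0("date,latitude,longitude,method,",
                    '"Aedes aegypti (individuals)","Culex pipiens (individuals)"'),
             "2017-06-04,41.66,-91.53,light trap,7,",
             "2017-06-11,41.66,-91.53,light trap,,0")
  p <- write_lines_csv(lines)
  unknown <- bind_columns(read_table(p), metadata = miread_metadata(
    absence_policy = "absent_means_unknown"))
  expect_equal(nrow(unknown$records), 2)  # empties produce nothing
  expect_true(any(grepl("absence policy", unknown$ingest_findings$message)))

  zero <- bind_columns(read_table(p), metadata = miread_metadata(
    absence_policy = "absent_means_zero"))
  expect_equal(nrow(zero$records), 4)
  expect_equal(sum(zero$records$value == 0), 3)
})

test_that("mapping configs bind arbitrary column names", {
  p <- write_lines_csv(c("when,who,howmany,wo",
                         "2017-06-04,Aedes aegypti,3,light trap"))
  cfg <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("layout: long", "bindings:", "  when: start_time",
               "  who: taxon", "  howmany: value",
               "  wo: collection_method"), cfg)
  ds <- bind_columns(read_table(p), read_mapping(cfg))
  expect_equal(ds$records$name, "Aedes aegypti")
  expect_equal(ds$records$value, 3)
  expect_equal(ds$events$collection_method, "light trap")
  # binding one concept twice is rejected
  expect_error(field_mapping(bindings = c(a = "value", b = "value")),
               class = "miread_invariant")
})

test_that("a table with no date column cannot bind", {
  p <- write_lines_csv(c("species,count", "Aedes aegypti,3"))
  expect_error(bind_columns(read_table(p), field_mapping(layout = "long")),
               class = "miread_missing_concept")
})
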