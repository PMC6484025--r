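# Synthetic surveillance scenarios. Four shapes cover the canonical ways
# arthropod abundance is reported: long-format trap catches, wide-format
# catches with a sub-location attribute, tick drags reporting three life
# stages (larvae only keyed to genus) linked by a sample name, and
# ectoparasites combed from trapped hosts with host attributes on the
# event. Counts follow a negative-binomial with a sinusoidal seasonal
# mean — the shape of real light-trap time series: overdispersed counts
# peaking mid-season.

SCENARIOS <- c("long_trap", "wide_subloc", "tick_drag", "host_ectoparasite")

#' Specify a synthetic surveillance scenario
#'
#' @param scenario One of `"long_trap"`, `"wide_subloc"`, `"tick_drag"`,
#'   `"host_ectoparasite"`.
#' @param n_events Number of sampling events (default 12: roughly a
#'   season of weekly trap nights).
#' @param n_taxa Number of taxa reported per event (capped by the
#'   embedded taxon pool; `tick_drag` uses one tick species complex and
#'   ignores this).
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   datasets.
#' @param mean_level Seasonal mean count at the peakless baseline
#'   (negative-binomial mean when `amplitude = 0`).
#' @param amplitude Relative seasonal amplitude in `[0, 1]`: the mean
#'   varies as `mean_level * (1 + amplitude * sin(phase))` over one
#'   annual cycle.
#' @param dispersion Negative-binomial size parameter; small values give
#'   the overdispersion typical of trap counts.
#' @return An object of class `miread_scenario`.
#' @export
scenario_spec <- function(scenario = SCENARIOS, n_events = 12, n_taxa = 3,
                          seed = 1, mean_level = 20, amplitude = 0.8,
                          dispersion = 2) {
  scenario <- match.arg(scenario)
  stopifnot(n_events >= 1, n_taxa >= 1, amplitude >= 0, amplitude <= 1)
  structure(list(scenario = scenario, n_events = as.integer(n_events),
                 n_taxa = as.integer(n_taxa), seed = as.integer(seed),
                 mean_level = mean_level, amplitude = amplitude,
                 dispersion = dispersion),
            class = "miread_scenario")
}

scenario_metadata <- function(spec) {
  desc <- switch(
    spec$scenario,
    long_trap = "Weekly adult mosquito monitoring with New Jersey light traps at fixed stations, one trap night per event.",
    wide_subloc = "Adult mosquito monitoring with CDC light traps at named sub-locations around a village, tracked over time.",
    tick_drag = "Tick surveillance by drag sampling of fixed transects; adults, nymphs and larvae counted separately.",
    host_ectoparasite = "Ectoparasites combed from live-trapped Peromyscus mice; one examination per captured host.")
  miread_metadata(
    contact = "Field Entomology Unit, surveillance@example.org",
    study_description = desc,
    citations = "Surveillance programme annual report, 2017",
    identification_method = "Morphological identification under stereomicroscope using regional keys",
    absence_policy = if (spec$scenario == "wide_subloc") "explicit_zeros"
                     else "absent_means_unknown",
    absence_note = if (spec$scenario == "wide_subloc") {
      "Zero means the taxon was looked for in the catch and not found."
    } else {
      "Taxa not listed for an event were not assessed."
    },
    usage_rights = "CC-BY 4.0"
  )
}

seasonal_counts <- function(n, spec) {
  phase <- 2 * pi * (seq_len(n) - 1) / max(n, 2)
  mu <- pmax(spec$mean_level * (1 + spec$amplitude * sin(phase)), 0.1)
  rnbinom(n, size = spec$dispersion, mu = mu)
}

#' Generate a synthetic scenario dataset
#'
#' Builds a complete, compliant dataset for the requested scenario:
#' full resource metadata, events with ISO dates, four-decimal
#' coordinates and documented methods, and seasonally varying
#' negative-binomial counts. The output validates clean by construction
#' and is the substrate for [corrupt_dataset()].
#'
#' @param spec A [scenario_spec()].
#' @return A `miread_dataset` (long layout, raw canonical table
#'   attached).
#' @examples
#' ds <- generate_scenario(scenario_spec("tick_drag", n_events = 4, seed = 7))
#' ds$records
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "miread_scenario"))
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)

  n <- spec$n_events
  base_date <- as.Date("2017-04-03")
  dates <- base_date + 7 * (seq_len(n) - 1)
  lat0 <- round(runif(1, 35, 45), 4)
  lon0 <- round(runif(1, -95, -75), 4)

  build <- switch(spec$scenario,
                  long_trap = build_long_trap,
                  wide_subloc = build_wide_subloc,
                  tick_drag = build_tick_drag,
                  host_ectoparasite = build_host_ecto)
  parts <- build(spec, dates, lat0, lon0)
  ds <- miread_dataset(metadata = scenario_metadata(spec),
                       events = parts$events, records = parts$records,
                       layout = "long")
  ds$raw <- canonical_raw(ds)
  ds
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# retain the generated dataset's own canonical table as its raw source, so
# structure-level rules have a surface to inspect (and to corrupt)
canonical_raw <- function(ds) {
  tab <- canonical_table(ds)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    vapply(as.list(tab[i, ]), function(v) {
      if (is.na(v)) "" else as.character(v)
    }, character(1))
  })
  structure(list(header = names(tab), rows = rows,
                 source_path = "<generated>",
                 dialect = list(delimiter = ",", encoding = "UTF-8"),
                 findings = empty_findings()),
            class = "miread_raw")
}

new_events <- function(spec, dates, lat0, lon0, method, attractants = NA,
                       area = NA, clocked = TRUE, jitter_coords = TRUE) {
  n <- length(dates)
  lat <- if (jitter_coords) round(lat0 + runif(n, -0.05, 0.05), 4) else rep(lat0, n)
  lon <- if (jitter_coords) round(lon0 + runif(n, -0.05, 0.05), 4) else rep(lon0, n)
  tibble(
    sample_id = sprintf("%s-%03d", toupper(substr(spec$scenario, 1, 2)),
                        seq_len(n)),
    sample_name = NA_character_,
    start_date = dates,
    start_clock = if (clocked) "18:00" else NA_character_,
    end_date = if (clocked) dates + 1 else dates,
    end_clock = if (clocked) "06:00" else NA_character_,
    start_raw = format(dates, "%Y-%m-%d"),
    end_raw = format(if (clocked) dates + 1 else dates, "%Y-%m-%d"),
    start_status = "ok", end_status = "ok",
    latitude = lat, longitude = lon,
    lat_raw = sprintf("%.4f", lat), lon_raw = sprintf("%.4f", lon),
    locality_text = NA_character_,
    collection_method = method,
    attractants = attractants,
    collection_area = area,
    additional_info = rep(list(character()), n)
  )
}

build_long_trap <- function(spec, dates, lat0, lon0) {
  taxa <- TAXON_POOL$mosquito[seq_len(min(spec$n_taxa,
                                          length(TAXON_POOL$mosquito)))]
  events <- new_events(spec, dates, lat0, lon0,
                       method = "New Jersey light trap",
                       attractants = "light",
                       area = "1 trap-night")
  records <- purrr::map_dfr(taxa, function(tx) {
    tibble(event_ref = events$sample_id, rank = "species", name = tx,
           sex = "female", life_stage = "adult",
           value = as.numeric(seasonal_counts(length(dates), spec)),
           unit = "individuals", sample_name = NA_character_)
  })
  records <- arrange(records, .data$event_ref, .data$name)
  list(events = events, records = records)
}

build_wide_subloc <- function(spec, dates, lat0, lon0) {
  taxa <- TAXON_POOL$mosquito[seq_len(min(spec$n_taxa,
                                          length(TAXON_POOL$mosquito)))]
  sublocs <- c("cattle shed", "market square", "school yard", "rice field")
  events <- new_events(spec, dates, lat0, lon0,
                       method = "CDC light trap",
                       attractants = "light",
                       area = "1 trap-night")
  events$additional_info <- lapply(seq_along(dates), function(i) {
    c("sub-location" = sublocs[1 + (i - 1) %% length(sublocs)])
  })
  records <- purrr::map_dfr(taxa, function(tx) {
    tibble(event_ref = events$sample_id, rank = "species", name = tx,
           sex = "female", life_stage = "adult",
           value = as.numeric(seasonal_counts(length(dates), spec)),
           unit = "individuals", sample_name = NA_character_)
  })
  records <- arrange(records, .data$event_ref, .data$name)
  list(events = events, records = records)
}

build_tick_drag <- function(spec, dates, lat0, lon0) {
  species <- TAXON_POOL$tick[1]
  genus <- strsplit(species, " ")[[1]][1]
  events <- new_events(spec, dates, lat0, lon0,
                       method = "tick drag along fixed transect",
                       area = "200 square meters", clocked = FALSE)
  events$sample_name <- sprintf("drag-%03d", seq_along(dates))
  records <- purrr::map_dfr(seq_along(dates), function(i) {
    counts <- seasonal_counts(3, spec)
    # larvae outnumber later stages roughly tenfold in drag samples
    bind_rows(
      tibble(event_ref = events$sample_id[i], rank = "species",
             name = species, sex = "unknown", life_stage = "adult",
             value = as.numeric(counts[1]), unit = "individuals",
             sample_name = events$sample_name[i]),
      tibble(event_ref = events$sample_id[i], rank = "species",
             name = species, sex = "unknown", life_stage = "nymph",
             value = as.numeric(counts[2]), unit = "individuals",
             sample_name = events$sample_name[i]),
      tibble(event_ref = events$sample_id[i], rank = "genus",
             name = genus, sex = "unknown", life_stage = "larva",
             value = as.numeric(counts[3] * 10), unit = "individuals",
             sample_name = events$sample_name[i])
    )
  })
  list(events = events, records = records)
}

build_host_ecto <- function(spec, dates, lat0, lon0) {
  taxa <- TAXON_POOL$flea[seq_len(min(spec$n_taxa, length(TAXON_POOL$flea)))]
  events <- new_events(spec, dates, lat0, lon0,
                       method = "ectoparasite combing of live-trapped Peromyscus mouse",
                       clocked = FALSE)
  events$sample_name <- sprintf("mouse-%03d", seq_along(dates))
  events$additional_info <- lapply(seq_along(dates), function(i) {
    c("host species" = "Peromyscus leucopus",
      "host sex" = sample(c("female", "male"), 1))
  })
  records <- purrr::map_dfr(taxa, function(tx) {
    tibble(event_ref = events$sample_id, rank = "species", name = tx,
           sex = "unknown", life_stage = "adult",
           value = as.numeric(rnbinom(length(dates), size = spec$dispersion,
                                      mu = spec$mean_level / 4)),
           unit = "individuals", sample_name = events$sample_name)
  })
  records <- arrange(records, .data$event_ref, .data$name)
  list(events = events, records = records)
}

#' Inject faults into a clean dataset
#'
#' Applies one minimal, localized corruption per requested rule class and
#' returns the corrupted dataset together with a ledger enumerating
#' exactly what was injected where — the ground truth for validator
#' recall tests. Example injections: an ambiguous numeric date (date
#' rule), a blanked metadata field (completeness rules), latitude 95
#' (coordinate rule), a duplicated record cell (duplicate rule).
#'
#' @param dataset A clean `miread_dataset` (from [generate_scenario()]).
#' @param faults Character vector of rule ids to inject (see
#'   `names(miread:::RULE_SEVERITY)`), or `"all"`.
#' @param seed Integer seed choosing injection sites.
#' @return A list: `dataset` (corrupted) and `ledger` (tibble `rule_id`,
#'   `row`, `column`).
#' @export
corrupt_dataset <- function(dataset, faults, seed = 1) {
  stopifnot(inherits(dataset, "miread_dataset"))
  if (identical(faults, "all")) faults <- names(RULE_SEVERITY)
  unknown <- setdiff(faults, names(RULE_SEVERITY))
  if (length(unknown)) {
    abort(paste0("unknown fault class: ", paste(unknown, collapse = ", ")),
          class = "miread_inapplicable_fault")
  }
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  ledger <- tibble(rule_id = character(), row = integer(),
                   column = character())
  note <- function(rule_id, row = NA_integer_, column = NA_character_) {
    ledger <<- bind_rows(ledger, tibble(rule_id = rule_id,
                                        row = as.integer(row),
                                        column = column))
  }
  n_ev <- nrow(dataset$events)
  n_rec <- nrow(dataset$records)
  # distinct injection sites so co-injected faults cannot overwrite each
  # other (e.g. a bad coordinate erased by a removed-coordinates fault)
  used_ev <- integer(); used_rec <- integer()
  pick_ev <- function() {
    free <- setdiff(seq_len(n_ev), used_ev)
    if (!length(free)) free <- seq_len(n_ev)
    i <- if (length(free) == 1) free else sample(free, 1)
    used_ev <<- c(used_ev, i)
    i
  }
  pick_rec <- function() {
    free <- setdiff(seq_len(n_rec), used_rec)
    if (!length(free)) free <- seq_len(n_rec)
    i <- if (length(free) == 1) free else sample(free, 1)
    used_rec <<- c(used_rec, i)
    i
  }

  for (fault in sort(unique(faults))) {
    switch(
      fault,
      R1_ABBREV = {
        i <- pick_ev()
        dataset$events$collection_method[i] <- "Lt. trap"
        note(fault, i, "collection_method")
      },
      R2_EXTERNAL_KEY = {
        i <- pick_ev()
        dataset$events$latitude[i] <- NA_real_
        dataset$events$longitude[i] <- NA_real_
        dataset$events$lat_raw[i] <- NA_character_
        dataset$events$lon_raw[i] <- NA_character_
        dataset$events$locality_text[i] <- "site_07"
        note(fault, i, "locality_text")
      },
      R3_DATE = {
        i <- pick_ev()
        parsed <- parse_date("04/06/2017")
        dataset$events$start_raw[i] <- parsed$input
        dataset$events$start_status[i] <- parsed$status
        note(fault, i, "start_time")
      },
      R4_FORMAT = {
        dataset$ingest_findings <- add_finding(
          dataset$ingest_findings, "R4_FORMAT", "warning",
          message = "file was not valid UTF-8; decoded as latin1")
        note(fault)
      },
      R5_STYLING = {
        if (is.null(dataset$raw)) {
          abort("R5_STYLING needs a retained raw table",
                class = "miread_inapplicable_fault")
        }
        i <- sample.int(length(dataset$raw$rows) + 1, 1)
        heading <- c("June collections",
                     rep("", length(dataset$raw$header) - 1))
        dataset$raw$rows <- append(dataset$raw$rows, list(heading),
                                   after = i - 1)
        note(fault, i)
      },
      R6_PRECISION = {
        i <- pick_ev()
        dataset$events$latitude[i] <- round(dataset$events$latitude[i], 1)
        dataset$events$lat_raw[i] <-
          sprintf("%.1f", dataset$events$latitude[i])
        note(fault, i, "latitude")
      },
      R7_LANGUAGE = {
        i <- pick_ev()
        ai <- dataset$events$additional_info[[i]]
        ai[["espèce hôte"]] <- "souris"
        dataset$events$additional_info[[i]] <- ai
        note(fault, NA, "espèce hôte")  # locus is the field name itself
      },
      M1_CONTACT = { dataset$metadata$contact <- ""; note(fault, NA, "contact") },
      M2_STUDY_DESCRIPTION = {
        dataset$metadata$study_description <- ""
        note(fault, NA, "study_description")
      },
      M3_IDENTIFICATION_METHOD = {
        dataset$metadata$identification_method <- ""
        note(fault, NA, "identification_method")
      },
      M4_ABSENCE_POLICY = {
        dataset$metadata$absence_policy <- ""
        note(fault, NA, "absence_policy")
      },
      M5_USAGE_RIGHTS = {
        dataset$metadata$usage_rights <- ""
        note(fault, NA, "usage_rights")
      },
      M6_COLLECTION_METHOD = {
        i <- pick_ev()
        dataset$events$collection_method[i] <- ""
        note(fault, i, "collection_method")
      },
      D1_DUPLICATE_KEY = {
        i <- pick_rec()
        dup <- dataset$records[i, ]
        dup$value <- dup$value + 1
        dataset$records <- bind_rows(dataset$records, dup)
        note(fault, nrow(dataset$records), "record")
      },
      D2_RELATIVE_ABUNDANCE = {
        i <- pick_rec()
        dataset$records$unit[i] <- "relative abundance"
        note(fault, i, "unit")
      },
      D3_BAD_COORD = {
        i <- pick_ev()
        dataset$events$latitude[i] <- 95
        dataset$events$lat_raw[i] <- "95.0000"
        note(fault, i, "latitude")
      },
      D4_TIME_ORDER = {
        i <- pick_ev()
        dataset$events$start_date[i] <- dataset$events$end_date[i] + 3
        dataset$events$start_raw[i] <-
          format(dataset$events$start_date[i], "%Y-%m-%d")
        note(fault, i, "start_time")
      }
    )
  }
  list(dataset = dataset, ledger = ledger)
}

#' Write a scenario to CSV
#'
#' Materializes a generated scenario in its native layout: long scenarios
#' as the canonical long CSV, the wide scenario as a wide CSV. The file
#' re-ingests clean.
#'
#' @param spec A [scenario_spec()].
#' @param path Output path.
#' @return The generated dataset, invisibly.
#' @export
write_scenario_csv <- function(spec, path) {
  ds <- generate_scenario(spec)
  if (spec$scenario == "wide_subloc") {
    write_wide_csv(ds, path)
  } else {
    write_canonical_csv(ds, path)
  }
  write_metadata(ds$metadata, paste0(path, ".metadata.yml"))
  invisible(ds)
}
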