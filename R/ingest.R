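#' Read a delimited abundance table
#'
#' Reads a machine-readable delimited text file (comma, tab or semicolon
#' separated; the delimiter is sniffed from the header line unless given).
#' All cells are kept as strings: typing happens at binding time, so that
#' findings can point at the offending source text. Binary input (PDF,
#' spreadsheet containers) is refused — abundance data must be submitted
#' in non-proprietary machine-readable form — and tables whose rows do
#' not all share the header's arity are refused as ragged. A blank line
#' followed by more content marks a second sub-table in one file, which
#' is recorded as a structure finding.
#'
#' @param path Path to the delimited text file.
#' @param delimiter Optional explicit delimiter (`","`, `"\t"` or `";"`).
#' @return An object of class `miread_raw`: list with `header` (character),
#'   `rows` (list of character vectors), `source_path`, `dialect`
#'   (delimiter + encoding) and `findings` (structure findings collected
#'   while reading).
#' @export
read_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) {
    abort(paste0("input not found: ", path), class = "miread_io")
  }
  head_bytes <- readBin(path, "raw", n = 8192L)
  if (length(head_bytes) >= 4 &&
      (rawToChar(head_bytes[1:4]) == "%PDF" ||
       identical(head_bytes[1:4], as.raw(c(0x50, 0x4b, 0x03, 0x04))) ||
       any(head_bytes == as.raw(0)))) {
    abort(paste0("not a machine-readable delimited text file: ", path),
          class = "miread_not_machine_readable")
  }

  findings <- empty_findings()
  txt <- rawToChar(readBin(path, "raw", file.size(path)))
  encoding <- "UTF-8"
  if (!validUTF8(txt)) {
    txt <- iconv(txt, from = "latin1", to = "UTF-8")
    encoding <- "latin1 (detected fallback)"
    findings <- add_finding(findings, "R4_FORMAT", "warning",
                            message = "file was not valid UTF-8; decoded as latin1")
  }
  Encoding(txt) <- "UTF-8"
  lines <- strsplit(txt, "\r\n|\n|\r")[[1]]
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    abort(paste0("empty input: ", path), class = "miread_io")
  }

  if (is.null(delimiter)) delimiter <- sniff_delimiter(lines[[1]])

  # a blank row followed by further content = a second block (sub-tables
  # in one document are a structure violation)
  blank <- !nzchar(trimws(lines))
  if (any(blank) && any(!blank & seq_along(lines) > which(blank)[1])) {
    findings <- add_finding(
      findings, "R5_STYLING", "error", row = which(blank)[1],
      message = "blank-row-delimited second block: one table per file")
  }
  lines <- lines[!blank]

  cells <- parse_delim_lines(lines, delimiter)
  header <- stringr::str_squish(cells[[1]])
  rows <- cells[-1]
  arity <- lengths(rows)
  if (length(rows) && any(arity != length(header))) {
    bad <- which(arity != length(header))[1]
    abort(sprintf("ragged table: row %d has %d cells, header has %d",
                  bad, arity[bad], length(header)),
          class = "miread_ragged")
  }
  if (anyDuplicated(header)) {
    abort(paste0("duplicate column names: ",
                 paste(header[duplicated(header)], collapse = ", ")),
          class = "miread_io")
  }
  structure(
    list(header = header, rows = rows, source_path = path,
         dialect = list(delimiter = delimiter, encoding = encoding),
         findings = findings),
    class = "miread_raw"
  )
}

#' @export
print.miread_raw <- function(x, ...) {
  cat(sprintf("<miread_raw> %d columns x %d data rows ('%s'-delimited, %s)\n",
              length(x$header), length(x$rows),
              if (x$dialect$delimiter == "\t") "\\t" else x$dialect$delimiter,
              x$dialect$encoding))
  cat("  columns:", paste(x$header, collapse = ", "), "\n")
  invisible(x)
}

sniff_delimiter <- function(header_line) {
  candidates <- c(",", "\t", ";")
  counts <- vapply(candidates, function(d) {
    length(parse_delim_lines(header_line, d)[[1]]) - 1L
  }, integer(1))
  if (all(counts == 0)) return(",")
  candidates[which.max(counts)]
}

# RFC-4180-ish: honours double-quoted fields with embedded delimiters and
# doubled quotes; one record per physical line
parse_delim_lines <- function(lines, delimiter) {
  lapply(lines, function(line) {
    sc <- scan(text = line, what = character(), sep = delimiter,
               quote = "\"", quiet = TRUE, strip.white = FALSE,
               blank.lines.skip = FALSE)
    if (!length(sc)) "" else sc
  })
}

#' Declare how source columns map to standard concepts
#'
#' The standard deliberately mandates no field names, so a submission's
#' columns must be bound to its concepts. A `field_mapping` does this
#' declaratively; anything left unbound falls back to built-in,
#' case-insensitive header heuristics (date/latitude/species/count/...).
#'
#' @param layout `"long"` (one row per taxon x event), `"wide"` (one
#'   column per taxon group) or `"auto"` (detect).
#' @param bindings Named character vector: source column name -> concept.
#'   Concepts are the event/record field names
#'   (`sample_id`, `sample_name`, `start_time`, `end_time`, `latitude`,
#'   `longitude`, `locality_text`, `collection_method`, `attractants`,
#'   `collection_area`, `taxon`, `taxon_rank`, `sex`, `life_stage`,
#'   `value`, `unit`),
#'   `"taxon_column"` for a per-taxon value column in wide layout,
#'   `"additional_info"`, or `"ignore"`.
#' @param vocab Named list of synonym maps, entries `sex` and
#'   `life_stage`, each a named character vector mapped over the built-in
#'   synonyms.
#' @param absence_policy Optional override of the metadata's absence
#'   policy, applied to empty wide-layout cells.
#' @return An object of class `miread_mapping`.
#' @export
field_mapping <- function(layout = c("auto", "long", "wide"),
                          bindings = character(),
                          vocab = list(),
                          absence_policy = NULL) {
  layout <- match.arg(layout)
  bindings <- unlist(bindings) %||% character()
  single <- unname(bindings)
  single <- single[!single %in% c("taxon_column", "additional_info", "ignore")]
  if (anyDuplicated(single)) {
    abort(paste0("concept bound more than once: ",
                 paste(unique(single[duplicated(single)]), collapse = ", ")),
          class = "miread_invariant")
  }
  if (layout == "wide" && length(bindings) &&
      !any(bindings == "taxon_column")) {
    abort("a wide-layout mapping must declare at least one taxon column",
          class = "miread_invariant")
  }
  structure(list(layout = layout, bindings = bindings, vocab = vocab,
                 absence_policy = absence_policy),
            class = "miread_mapping")
}

#' Read a mapping configuration file
#'
#' Mapping configs are YAML or JSON documents with keys `layout`,
#' `bindings`, `vocab` and `absence_policy`, mirroring the arguments of
#' [field_mapping()].
#'
#' @param path Path to a `.yml`/`.yaml`/`.json` file.
#' @return A `miread_mapping`.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("mapping config not found: ", path), class = "miread_io")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  field_mapping(layout = cfg$layout %||% "auto",
                bindings = unlist(cfg$bindings) %||% character(),
                vocab = cfg$vocab %||% list(),
                absence_policy = cfg$absence_policy)
}

# header heuristics: regex -> concept, tried in order, case-insensitive
HEADER_HEURISTICS <- c(
  "^(sample|event)[ ._-]?id$" = "sample_id",
  "^sample[ ._-]?name$" = "sample_name",
  "^(start|collection)?[ ._-]?(date|start)( ?time)?$" = "start_time",
  "^start" = "start_time",
  "^end" = "end_time",
  "^lat(itude)?$" = "latitude",
  "^lon(g(itude)?)?$|^lng$" = "longitude",
  "^(taxon[ ._-]?)?rank$" = "taxon_rank",
  "species|taxon|scientific" = "taxon",
  "^sex$" = "sex",
  "stage" = "life_stage",
  "^(count|number|value|abundance|total|n)$" = "value",
  "^unit" = "unit",
  "method|trap|protocol" = "collection_method",
  "attract" = "attractants",
  "area|effort" = "collection_area",
  "^(locality|location|site|place)" = "locality_text"
)

resolve_bindings <- function(header, mapping) {
  concept <- unname(mapping$bindings[header])
  for (i in seq_along(header)) {
    if (!is.na(concept[i])) next
    for (j in seq_along(HEADER_HEURISTICS)) {
      if (grepl(names(HEADER_HEURISTICS)[j], header[i], ignore.case = TRUE)) {
        concept[i] <- unname(HEADER_HEURISTICS[j])
        break
      }
    }
    # a column whose (annotation-stripped) header looks like a taxon is a
    # wide-layout per-taxon value column
    if (is.na(concept[i]) && looks_like_taxon_header(header[i])) {
      concept[i] <- "taxon_column"
    }
  }
  # heuristics must not bind one concept twice; later duplicates unbind
  single <- !concept %in% c("taxon_column", "additional_info", "ignore")
  dup <- single & duplicated(concept) & !is.na(concept)
  concept[dup] <- NA_character_
  concept
}

looks_like_taxon_header <- function(h) {
  name <- parse_taxon_header(h)$name
  toks <- strsplit(name, " ")[[1]]
  if (!length(toks)) return(FALSE)
  genus_like <- grepl("^[A-Z][a-z]+$", toks[1])
  binomial <- length(toks) >= 2 && genus_like &&
    all(grepl("^[a-z]+$", toks[-1]))
  genus_like && (binomial || toks[1] %in% KNOWN_GENERA)
}

# wide-layout header convention: "Taxon name[, sex][, stage] (unit)"
parse_taxon_header <- function(h) {
  h <- stringr::str_squish(h)
  unit <- stringr::str_match(h, "\\(([^()]*)\\)\\s*$")[, 2]
  body <- stringr::str_squish(sub("\\(([^()]*)\\)\\s*$", "", h))
  parts <- stringr::str_squish(strsplit(body, ",")[[1]])
  parts <- parts[nzchar(parts)]
  name <- if (length(parts)) parts[1] else ""
  sex <- "unknown"; stage <- "unknown"; leftover <- character()
  for (p in parts[-1]) {
    key <- tolower(p)
    if (normalize_sex(key) != "unknown" || key %in% c("unknown sex")) {
      sex <- normalize_sex(key)
    } else if (normalize_life_stage(key) != "unknown") {
      stage <- normalize_life_stage(key)
    } else {
      leftover <- c(leftover, p)
    }
  }
  list(name = name, sex = sex, life_stage = stage,
       unit = if (is.na(unit) || !nzchar(unit)) "individuals" else unit,
       parsed = length(leftover) == 0 && nzchar(name))
}

#' Detect long versus wide layout
#'
#' A long table binds exactly one taxon-name column plus one value column;
#' a wide table binds one or more per-taxon value columns. When neither
#' signature matches the layout cannot be inferred and an explicit mapping
#' is required.
#'
#' @param table A `miread_raw` from [read_table()].
#' @param mapping A `miread_mapping` (layout `"auto"`).
#' @return `"long"` or `"wide"`.
#' @export
detect_layout <- function(table, mapping = field_mapping()) {
  if (mapping$layout != "auto") return(mapping$layout)
  concept <- resolve_bindings(table$header, mapping)
  n_taxon_cols <- sum(concept == "taxon_column", na.rm = TRUE)
  has_taxon <- any(concept == "taxon", na.rm = TRUE)
  has_value <- any(concept == "value", na.rm = TRUE)
  if (has_taxon && has_value) return("long")
  if (n_taxon_cols >= 1) return("wide")
  abort(paste0("cannot tell long from wide layout for columns: ",
               paste(table$header, collapse = ", "),
               "; provide an explicit mapping"),
        class = "miread_ambiguous_layout")
}

#' Bind source columns to a dataset
#'
#' Builds a [miread_dataset()] from a raw table: one sampling event per
#' distinct event key (long layout) or per row (wide layout), and one
#' abundance record per long row or per non-empty wide cell. Every source
#' column ends up either bound to a concept, parsed as a taxon column,
#' preserved under the event's `additional_info`, or explicitly ignored;
#' columns the heuristics could not place are preserved under
#' `additional_info` *and* reported in an unbound-column finding — no
#' cell is ever silently dropped.
#'
#' @param table A `miread_raw`.
#' @param mapping A `miread_mapping`.
#' @param metadata A [miread_metadata()] for the dataset.
#' @return A `miread_dataset` with ingest findings attached.
#' @export
bind_columns <- function(table, mapping = field_mapping(),
                         metadata = miread_metadata()) {
  layout <- detect_layout(table, mapping)
  concept <- resolve_bindings(table$header, mapping)
  findings <- table$findings
  findings <- add_finding(findings, "R4_FORMAT", "info",
                          message = sprintf("layout detected: %s", layout))

  unbound <- which(is.na(concept))
  for (i in unbound) {
    findings <- add_finding(
      findings, "R4_FORMAT", "warning", column = table$header[i],
      message = sprintf(
        "unbound column '%s' preserved as additional information",
        table$header[i]))
    concept[i] <- "additional_info"
  }
  if (!any(concept == "start_time")) {
    abort("no date column could be bound", class = "miread_missing_concept")
  }
  if (layout == "long" &&
      (!any(concept == "taxon") || !any(concept == "value"))) {
    abort("long layout needs a taxon column and a value column",
          class = "miread_missing_concept")
  }

  cells <- do.call(rbind, table$rows)
  if (is.null(cells)) cells <- matrix(character(), ncol = length(table$header))
  colnames(cells) <- table$header
  df <- as_tibble(cells, .name_repair = "minimal")

  col_of <- function(role) {
    idx <- which(concept == role)
    if (length(idx)) df[[idx[1]]] else rep(NA_character_, nrow(df))
  }

  start <- parse_date(col_of("start_time"))
  end_raw_col <- col_of("end_time")
  end <- parse_date(ifelse(is.na(end_raw_col) | !nzchar(end_raw_col),
                           col_of("start_time"), end_raw_col))

  info_cols <- which(concept == "additional_info")
  additional <- lapply(seq_len(nrow(df)), function(r) {
    if (!length(info_cols)) return(character())
    setNames(as.character(cells[r, info_cols]), table$header[info_cols])
  })

  ev <- tibble(
    sample_id = col_of("sample_id"),
    sample_name = col_of("sample_name"),
    start_date = start$date, start_clock = start$clock,
    end_date = end$date, end_clock = end$clock,
    start_raw = start$input, end_raw = end$input,
    start_status = start$status, end_status = end$status,
    latitude = suppressWarnings(as.numeric(col_of("latitude"))),
    longitude = suppressWarnings(as.numeric(col_of("longitude"))),
    lat_raw = col_of("latitude"), lon_raw = col_of("longitude"),
    locality_text = col_of("locality_text"),
    collection_method = col_of("collection_method"),
    attractants = col_of("attractants"),
    collection_area = col_of("collection_area"),
    additional_info = additional
  )

  syn <- mapping$vocab
  if (layout == "long") {
    events <- ev
    if (all(is.na(events$sample_id))) {
      # long rows sharing (start, place) belong to one sampling event
      key <- paste(ev$start_raw, ev$end_raw, ev$lat_raw, ev$lon_raw,
                   ev$locality_text, ev$collection_method,
                   vapply(ev$additional_info, paste, character(1),
                          collapse = "|"),
                   sep = "\x1f")
      events$sample_id <- paste0("ev", match(key, unique(key)))
      findings <- add_finding(
        findings, "R4_FORMAT", "info",
        message = "sample_id auto-generated from distinct event keys")
    }
    records <- tibble(
      event_ref = events$sample_id,
      name = stringr::str_squish(col_of("taxon")),
      sex = normalize_sex(col_of("sex"), syn$sex),
      life_stage = normalize_life_stage(col_of("life_stage"), syn$life_stage),
      value = suppressWarnings(as.numeric(col_of("value"))),
      unit = {
        u <- col_of("unit")
        ifelse(is.na(u) | !nzchar(u), "individuals", u)
      },
      sample_name = events$sample_name
    )
    ranks <- purrr::map_chr(records$name, function(nm) {
      toks <- strsplit(nm, " ")[[1]]
      n <- sum(nzchar(toks))
      if (n >= 3) "subspecies" else if (n == 2) "species" else "genus"
    })
    stated <- tolower(trimws(col_of("taxon_rank")))
    ranks <- ifelse(!is.na(stated) & stated %in% RANK_LEVELS, stated, ranks)
    records <- mutate(records, rank = ranks, .after = "event_ref")
    events <- distinct(events, .data$sample_id, .keep_all = TRUE)
  } else {
    events <- ev
    if (all(is.na(events$sample_id))) {
      events$sample_id <- paste0("ev", seq_len(nrow(events)))
      findings <- add_finding(findings, "R4_FORMAT", "info",
                              message = "sample_id auto-generated per row")
    }
    taxon_cols <- which(concept == "taxon_column")
    policy <- mapping$absence_policy %||% metadata$absence_policy
    recs <- list()
    for (tc in taxon_cols) {
      th <- parse_taxon_header(table$header[tc])
      if (!th$parsed) {
        findings <- add_finding(
          findings, "R4_FORMAT", "warning", column = table$header[tc],
          message = sprintf(
            "taxon column '%s' only partially parsed; sex/stage set to unknown",
            table$header[tc]))
      }
      raw_vals <- as.character(cells[, tc])
      for (r in seq_len(nrow(events))) {
        v <- raw_vals[r]
        if (is.na(v) || !nzchar(trimws(v))) {
          if (identical(policy, "absent_means_zero")) {
            v <- "0"
          } else {
            findings <- add_finding(
              findings, "R4_FORMAT", "info", row = r,
              column = table$header[tc],
              message = sprintf(
                "empty cell (row %d, '%s') read as unknown under absence policy '%s'",
                r, table$header[tc], policy))
            next
          }
        }
        toks <- strsplit(th$name, " ")[[1]]
        recs[[length(recs) + 1L]] <- tibble(
          event_ref = events$sample_id[r],
          rank = if (length(toks) >= 3) "subspecies"
                 else if (length(toks) == 2) "species" else "genus",
          name = th$name, sex = th$sex, life_stage = th$life_stage,
          value = suppressWarnings(as.numeric(v)), unit = th$unit,
          sample_name = events$sample_name[r]
        )
      }
    }
    records <- if (length(recs)) bind_rows(recs) else empty_records()
  }

  miread_dataset(metadata = metadata, events = events, records = records,
                 layout = layout, raw = table, ingest_findings = findings)
}
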