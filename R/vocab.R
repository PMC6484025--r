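# Controlled internal vocabularies. The standard itself mandates no
# vocabulary or field names; these canonical forms exist so that records can
# be compared, deduplicated and pivoted. Ingestion maps free text onto them
# case-insensitively and user mappings can extend the synonym tables.

SEX_LEVELS <- c("female", "male", "mixed", "unknown")
LIFE_STAGE_LEVELS <- c("egg", "larva", "nymph", "pupa", "adult", "mixed", "unknown")
RANK_LEVELS <- c("kingdom", "phylum", "class", "order", "family", "genus",
                 "species", "subspecies")
ABSENCE_POLICIES <- c("explicit_zeros", "absent_means_unknown", "absent_means_zero")

default_sex_synonyms <- function() {
  c("f" = "female", "female" = "female", "females" = "female", "♀" = "female",
    "m" = "male", "male" = "male", "males" = "male", "♂" = "male",
    "mixed" = "mixed", "mixed sex" = "mixed", "mixed-sex" = "mixed",
    "both" = "mixed", "unknown" = "unknown", "unk" = "unknown",
    "undetermined" = "unknown", "na" = "unknown")
}

default_stage_synonyms <- function() {
  c("egg" = "egg", "eggs" = "egg",
    "larva" = "larva", "larvae" = "larva", "larval" = "larva",
    "nymph" = "nymph", "nymphs" = "nymph", "nymphal" = "nymph",
    "pupa" = "pupa", "pupae" = "pupa",
    "adult" = "adult", "adults" = "adult", "imago" = "adult",
    "mixed" = "mixed", "all stages" = "mixed",
    "unknown" = "unknown", "unk" = "unknown", "na" = "unknown")
}

#' Normalize sex and life-stage labels
#'
#' Maps free-text sex and life-stage labels onto the package's canonical
#' levels (`female/male/mixed/unknown` and
#' `egg/larva/nymph/pupa/adult/mixed/unknown`). Matching is case-insensitive
#' and whitespace-insensitive; unrecognized labels become `"unknown"`.
#'
#' @param x Character vector of labels.
#' @param synonyms Optional named character vector of extra synonym -> level
#'   pairs, merged over the built-in table (e.g. from a mapping config).
#' @return Character vector of canonical levels, same length as `x`.
#' @examples
#' normalize_sex(c("F", "Females", "?"))
#' normalize_life_stage(c("Larvae", "ADULT"))
#' @export
normalize_sex <- function(x, synonyms = NULL) {
  normalize_label(x, default_sex_synonyms(), synonyms)
}

#' @rdname normalize_sex
#' @export
normalize_life_stage <- function(x, synonyms = NULL) {
  normalize_label(x, default_stage_synonyms(), synonyms)
}

normalize_label <- function(x, table, extra = NULL) {
  if (!is.null(extra)) table[tolower(names(extra))] <- unname(extra)
  key <- stringr::str_squish(tolower(as.character(x)))
  key[is.na(key)] <- ""
  out <- unname(table[key])
  out[is.na(out)] <- "unknown"
  out
}

# Trap/method acronyms and unit tokens exempt from the no-abbreviations rule.
# Measurement units are explicitly exempt; trap acronyms (CDC, BG, ...) are
# established proper names in vector surveillance, not ad-hoc shorthand.
ABBREV_LEXICON <- c(
  "CDC", "BG", "EVS", "NJLT", "UV", "CO2", "USA", "UK", "WGS84", "GPS", "ID",
  "C", "F", "K", "M", "KM", "CM", "MM", "HA", "ISO"
)

# Small embedded list of real vector taxa used by the scenario generator and
# by the wide-layout taxon-column heuristic. Data, not logic.
TAXON_POOL <- list(
  mosquito = c("Aedes aegypti", "Aedes albopictus", "Culex pipiens",
               "Culex quinquefasciatus", "Anopheles gambiae",
               "Anopheles quadrimaculatus", "Culiseta melanura",
               "Psorophora columbiae"),
  tick = c("Ixodes scapularis", "Amblyomma americanum",
           "Dermacentor variabilis", "Rhipicephalus sanguineus"),
  flea = c("Ctenocephalides felis", "Orchopeas leucopus",
           "Ctenophthalmus pseudagyrtes")
)

KNOWN_GENERA <- unique(vapply(strsplit(unlist(TAXON_POOL), " "),
                              `[[`, character(1), 1))
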