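---
title: "Validating and publishing arthropod abundance data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and publishing arthropod abundance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miread)
```

## The problem

Arthropod abundance time series are the empirical backbone of vector-borne
disease modelling, pest management and phenology research, but most field
datasets cannot be reused by anyone who was not in the room when they were
collected. The failure modes are mundane and systematic: all-numeric dates
whose day and month cannot be told apart, site codes whose coordinates
live in somebody's drawer, counts that are secretly relative indices,
spreadsheets whose meaning depends on subsection headings, and silence on
whether an absent taxon was *counted as zero* or *never looked for*.

A minimum-information standard attacks this by listing what a submission
must carry — while deliberately **not** mandating field names, field order
or controlled vocabularies, so that compliance is cheap for data
generators. `miread` implements that standard as software: a data model,
a rule engine, layout normalization, and an exporter to Darwin Core, the
vocabulary biodiversity aggregators ingest.

## The data model

A submission has two components.

**Resource metadata** is dataset-level: contact, study description,
citations, species identification method, the absence policy, GPS
obfuscation (with datum), usage rights, language. Five of these —
contact, study description, identification method, absence policy and
usage rights — are required for compliance; the rest are context.

The **absence policy** is modelled as a three-level factor because the
standard requires the *information* but not its form:

* `explicit_zeros` — zeros are written out; absence from the table is
  impossible.
* `absent_means_zero` — a missing taxon/event cell was assessed and empty.
* `absent_means_unknown` — a missing cell was never assessed.

The free-text elaboration is preserved alongside. This distinction
propagates end to end: empty wide-layout cells materialize as value-0
records only under a zero-meaning policy, and `occurrenceStatus` in the
Darwin Core export is `"absent"` exactly when the value is 0.

**Data** decomposes into *sampling events* (one collection act: times,
place, method, attractants, effort, free-form additional attributes) and
*abundance records* (one observed quantity: event reference, taxonomic
assignment with sex and life stage, value, unit). The canonical identity
of a record is the tuple (event, rank, name, sex, life stage, unit) —
case-folded, enums normalized, value excluded. Two records sharing that
key are one cell reported twice, which is an error, never two
observations.

Taxonomic rank is inferred from token count (one token genus, two
species, three subspecies) and never guesses an epithet; single-letter
abbreviated genera are rejected outright because under the
no-abbreviations rule they are unrecoverable. Genus-only assignments are
first-class — tick larvae routinely cannot be keyed below genus while
adults from the same drag can.

Two construction regimes coexist deliberately. User-facing constructors
(`sampling_event()`, `abundance_record()`) enforce invariants — latitude
in [−90, 90], start not after end, non-negative values — and name the
violated invariant. Ingestion and the fault injector build rows without
those checks, because the validator's whole job is to *report* such
problems as findings on data that loaded structurally. Only referential
integrity (unique `sample_id`, resolving `event_ref`) is unconditionally
hard.

## The date grammar

Accepted as unambiguous: ISO 8601 (`2019-01-27`, optional time),
day–alphabetic-month–year (`4-Jun-2017`) and month day, year
(`Nov 12, 2015`), always with four-digit years. An all-numeric non-ISO
form is salvaged only when exactly one candidate field exceeds 12 and so
can only be the day (`25/06/2017` parses, flagged as a warning);
`04/06/2017` is rejected as ambiguous. We also reject the equal-field
case (`04/04/2017`), which is technically harmless but fails the
"one field forces the slot" criterion — a conservative tie-break that
keeps the rule statable in one sentence. Two-digit years always fail. The
grammar is total: an input either yields a date or a flag, never both.

## The rule engine

Findings carry a rule id, severity, location (row/column) and a message
naming the offending value; ordering is deterministic (rule, row, column)
so reports diff cleanly and serialize byte-identically. The severity
policy is principled rather than exhaustive: **errors** are reserved for
rules checkable without heuristics — completeness of the required
metadata and of per-event collection methods (M1–M6), date ambiguity
(R3), line-isolation violations (R5), external-key dependence (R2),
duplicate canonical keys (D1), relative-abundance units (D2), coordinate
range (D3), time order (D4), and contradiction of a declared coordinate
obfuscation (R6 escalates). **Warnings** cover the heuristic rules:
abbreviation detection (R1: dotted or short all-caps tokens outside a
unit-and-trap-name lexicon — "CDC light trap" is a proper name, not
shorthand), undeclared low coordinate precision (R6), non-ASCII field
names (R7 — other languages are explicitly better than unpublished data,
so it never blocks), and format provenance (R4: encoding fallbacks,
layout detection, auto-generated identifiers). Compliance is the absence
of errors; warnings never affect it.

Duplicate keys are reported, never collapsed: how to aggregate replicate
counts (and whether an arithmetic mean is even meaningful for
overdispersed abundance data) is the analyst's decision, not the
linter's.

## Layout normalization

Canonical form is long layout with unique canonical keys. Wide tables use
the header convention `Taxon name[, sex][, life stage] (unit)`; generated
wide tables order taxon columns alphabetically by (name, stage, sex) so
output is deterministic. Round-trips conserve the multiset of canonical
records and the total count; zeros asserted by the source are
materialized, not dropped. Composite records ("48 ticks, stages mixed")
split into per-class records sharing one sample name — possibly at
different ranks — only when per-class counts are supplied; a composite
that cannot be apportioned is kept whole with a warning, because
inventing an apportionment would be fabricating data. Host attributes
(the sex of a trapped mouse) attach to the event's additional
information, never to the arthropod's own sex field.

One subtlety found by testing: the canonical CSV writes dates back in ISO
form *except* those that failed the grammar, which are written verbatim —
otherwise normalizing a non-compliant file would silently launder its
ambiguous dates into compliance.

## Darwin Core export

The exporter implements two fixed routing tables (exposed by
`dwc_field_routing()` and asserted by an introspection test): seven
resource-metadata routings to the GBIF metadata profile (study
description and identification method both land in `designDescription`
as labelled subsections; the absence policy in `samplingDescription`;
obfuscation in `geographicDescription` + `geodeticDatum`; rights in
`intellectualRights`) and twelve data routings to Darwin Core terms.

The archive uses an **event core** with an occurrence extension, not an
occurrence core: the standard is sampling-event-centric, and it is the
documented collection act that makes an explicit zero meaningful.
`eventDate` collapses to a single date for same-day sampling and becomes
a `start/end` interval otherwise, clock times going to `eventTime`;
method and attractants combine into `samplingProtocol`; additional
attributes serialize as `key: value` pairs into both `fieldNotes` and
`eventRemarks` (the routing names both targets without a split
criterion, so both are emitted). `sampleSizeValue`/`sampleSizeUnit` are
duplicated into `organismQuantity`/`organismQuantityType` for aggregator
friendliness — an extension beyond the routing table, documented as
such. The datum defaults to WGS84 when the metadata names none.

Archives are written by a built-in stored-method ZIP writer with fixed
timestamps, so a fixed dataset yields a byte-identical archive on every
run and machine — determinism is part of the output contract, not a test
convenience.

## The scenario generator and what it does (not) show

Four scenarios mirror the canonical reporting shapes: `long_trap`
(one species-count per row), `wide_subloc` (taxon columns plus a
sub-location attribute, explicit zeros), `tick_drag` (adult/nymph/larva
reported independently, larvae at genus rank, linked by sample name) and
`host_ectoparasite` (host species and host sex as event attributes).
Counts are negative-binomial with a sinusoidal seasonal mean:
`mu(t) = mean_level * (1 + amplitude * sin(phase))`, defaults
`mean_level = 20`, `amplitude = 0.8`, `dispersion = 2` (size), 12 weekly
events — overdispersed counts peaking mid-season, the texture of real
light-trap series. The standard prescribes no abundance model; these are
this package's defaults, chosen once to look like a modest single-season
surveillance effort, and surfaced in `scenario_spec()` so tests control
them. Taxon names come from a small embedded list of real vector species.

The fault injector applies one minimal corruption per requested rule
class at randomly chosen, mutually distinct sites and returns a ledger of
(rule, row, column) — ground truth for recall testing. Distinct sites
matter: co-injected faults must not overwrite each other (a bad
coordinate erased by a removed-coordinate fault would make recall
unmeasurable).

What passing tests show: the validator recalls every rule class it
defines, at the right location, on data whose corruption is known
exactly; conversions conserve counts; exports are self-consistent and
deterministic. What they do not show: recall on the open-ended ways real
data goes wrong (handwriting-era transcription, merged spreadsheet cells,
vernacular names), heuristic precision on messy real headers, or
taxonomic validity — name resolution against external backbones is
explicitly out of scope.

## Numerical and degenerate-input choices

Coordinate precision is judged on the *stated* string (trailing zeros are
significant in a reported coordinate); a declared obfuscation like
"rounded to 0.1 degree" is parsed to decimal places and contradiction is
an error. Empty datasets export as header-plus-metadata archive shells.
Events with equal start and end are legal (cross-sectional sampling);
missing clock times compare as midnight so such events are not flagged.
Unbound columns are preserved as additional information *and* reported —
the conservation invariant is that every source cell is reachable in the
dataset or named in a finding. Problem sizes in the test suite (5–10
events, 2–3 taxa, 20 seeds for compliance, 100 random multi-fault
subsets) keep the full suite around twenty seconds while exercising every
rule exhaustively.

## A worked pass

```{r example}
ds <- generate_scenario(scenario_spec("tick_drag", n_events = 4, seed = 7))
dplyr::count(ds$records, rank, life_stage)

out <- corrupt_dataset(ds, c("R3_DATE", "D3_BAD_COORD"), seed = 1)
tidy(validate_dataset(out$dataset))[, 1:4]

z <- tempfile(fileext = ".zip")
write_dwca(ds, z)
utils::unzip(z, list = TRUE)$Name
```
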