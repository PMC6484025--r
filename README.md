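# miread

Validate, normalize and publish arthropod abundance data under the MIReAD
minimum-information standard.

Arthropod surveillance programmes — mosquito light-trap networks, tick
drags, ectoparasite surveys — produce spatially explicit count time series
that are rarely reusable: tables arrive in ad-hoc layouts, dates like
`04/06/2017` mean different days on different continents, and the metadata
needed to interpret a count (how specimens were identified, whether a
missing taxon means *zero* or *not assessed*, whether coordinates were
blurred for privacy) is usually missing. MIReAD (Minimum Information for
Reusable Arthropod Abundance Data) defines the least information such a
submission must carry; deliberately, it mandates **concepts, not field
names or vocabularies**.

`miread` is a toolchain for that standard, aimed at data managers,
surveillance programmes and aggregators:

* **ingest** — read delimited tables in *long* (one row per taxon ×
  sampling event) or *wide* (one column per taxon group) layout, bind
  arbitrary column names to MIReAD concepts via heuristics or a declarative
  mapping config, and parse dates under an unambiguity grammar (ISO 8601,
  `4-Jun-2017`, `Nov 12, 2015`; all-numeric forms only when a field > 12
  forces the day slot).
* **validate** — a rule engine covering the data-quality standards
  (no abbreviations, no external key files, unambiguous dates,
  machine-readable format, line-isolation/no headings, highest precision,
  language) plus minimum-information completeness and record-level checks
  (duplicate cells, relative-abundance units, coordinate ranges, time
  order). Output is an ordered findings table and a compliance verdict:
  compliant ⇔ zero error-severity findings.
* **normalize** — lossless long ↔ wide conversion with explicit
  zero-versus-unknown semantics, composite record splitting linked by
  sample name, and a canonical long interchange CSV.
* **export** — Darwin Core Archive (event core + occurrence extension,
  `meta.xml`, GBIF-profile `eml.xml`), byte-stable for a fixed dataset.
* **fixtures** — a seeded generator for four canonical scenarios
  (long trap counts; wide layout with sub-locations; tick drags with
  genus-level larvae; host ectoparasites) with negative-binomial seasonal
  counts, and a fault injector that corrupts a clean dataset one rule
  class at a time and returns a ledger — the ground truth for validator
  recall.

## Worked example

```r
library(miread)

spec <- scenario_spec("long_trap", n_events = 4, n_taxa = 2, seed = 1)
ds <- generate_scenario(spec)
ds
#> <miread_dataset> 4 events, 8 records (long layout)
#>   taxa: Aedes aegypti, Aedes albopictus
#>   dates: 2017-04-03 to 2017-04-25
glance(ds)
#> # A tibble: 1 × 7
#>   n_events n_records n_taxa total_count date_min   date_max   layout
#>      <int>     <int>  <int>       <dbl> <date>     <date>     <chr>
#> 1        4         8      2         132 2017-04-03 2017-04-25 long
```

Four trap nights, two species, 132 mosquitoes in total. Corrupt it the way
real submissions go wrong — an ambiguous numeric date and missing usage
rights — and validate:

```r
bad <- corrupt_dataset(ds, c("R3_DATE", "M5_USAGE_RIGHTS"), seed = 2)$dataset
validate_dataset(bad)
#> <miread_report> NOT COMPLIANT (2 error(s), 0 warning(s))
#>   [error] M5_USAGE_RIGHTS: required resource metadata 'usage_rights'
#>           (Data usage information) is missing
#>   [error] R3_DATE: date '04/06/2017' is ambiguous
```

A clean dataset exports straight to a Darwin Core Archive:

```r
write_dwca(ds, "long_trap.zip")   # event.txt, occurrence.txt, meta.xml, eml.xml
```

From a shell, the same pipeline (exit codes: 0 compliant, 1 violations,
2 I/O failure):

```sh
exec/miread fixture --scenario wide_subloc --seed 3 --out catch.csv
exec/miread validate catch.csv                # metadata sidecar auto-found
exec/miread convert catch.csv --to dwca --out catch.zip
```

Tabular data in, tibbles out: `ds$events`, `ds$records`,
`tidy(validate_dataset(ds))` all chain with dplyr, and
`autoplot(ds)` / `autoplot(report)` give first-look figures.

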