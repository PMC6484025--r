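Package: miread
Title: Validate, Normalize and Publish Arthropod Abundance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with arthropod abundance submissions under the
    MIReAD minimum-information standard (Minimum Information for Reusable
    Arthropod Abundance Data). Reads delimited tables in long or wide layout,
    binds arbitrary column names to standard concepts via a declarative
    mapping, detects ambiguous date formats, runs a rule engine covering the
    standard's data-quality rules and minimum-information completeness,
    converts between long and wide layouts without information loss, and
    exports compliant datasets to Darwin Core Archives (event core plus
    occurrence extension) with GBIF-profile EML metadata. Includes a seeded
    synthetic-data generator for four canonical surveillance scenarios and a
    fault injector for exercising the validator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
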