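Package: reportfmt
Title: Validate Environmental Dataset Bundles Against Community Reporting Formats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A schema-driven toolkit for the family of eleven community
    (meta)data reporting formats used to archive Earth and environmental
    science data: six cross-domain formats (dataset metadata, file-level
    metadata, CSV formatting guidelines, sample IDs and metadata, location
    metadata, terrestrial model data archiving) and five domain-specific
    formats (amplicon abundance tables, leaf-level gas exchange, soil
    respiration, water and soil chemistry, sonde-based hydrologic
    monitoring). Encodes each format as a machine-readable schema, validates
    multi-file dataset bundles against them with coded, located findings,
    maps terminology from external standards onto the harmonized terms via
    tabular crosswalks, and generates seeded synthetic bundles with
    controlled violation injection so every rule is testable offline.
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
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
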