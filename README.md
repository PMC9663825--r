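# reportfmt

Schema-driven validation for the family of eleven community (meta)data
reporting formats used to archive Earth and environmental science data.

Research datasets reach long-term repositories as *bundles*: CSV data
tables plus dataset-level citation metadata, a file-level metadata
(FLMD) table describing every file, sample and location registries, and
domain-specific tables (amplicon abundance matrices, leaf-level gas
exchange, soil respiration, water/soil chemistry, sonde-based hydrologic
series). Community reporting formats prescribe how each piece is shaped
— required columns, `YYYY-MM-DD` dates, decimal-degree coordinates in
the closed bounds ±90/±180, the `-9999` numeric missing sentinel,
controlled vocabularies — but checking is usually manual. reportfmt
encodes the formats as machine-readable schemas and automates it, for
data contributors who want to validate before submission and for
curators and pipelines that need a deterministic, coded report.

The package provides:

* a **schema registry** of the 11 formats (6 cross-domain:
  `dataset_metadata`, `file_level_metadata`, `csv_guidelines`,
  `sample_metadata`, `location_metadata`, `model_archiving`;
  5 domain-specific: `amplicon_abundance`, `leaf_gas_exchange`,
  `soil_respiration`, `water_soil_chemistry`, `hydrologic_monitoring`),
  with a recommender that walks the applicability workflow
  (`recommend_formats()`);
* a **table validation engine** (`validate_table()`,
  `validate_domain_table()`, `validate_bundle()`) producing coded,
  located findings — e.g. `REQ-MISSING`, `COORD-BOUNDS`, `MIXED-TYPE`,
  `HYD-TIME-ORDER` — in tidy `validation_report` objects with
  `tidy()`/`glance()`/`autoplot()` methods and a canonical JSON form;
* **crosswalks** mapping external-standard terminology (e.g. a foreign
  `ValueDateTime` column) onto the harmonized terms, with affine unit
  conversion, plus a ten-instrument translation table for leaf-level
  gas-exchange output (`map_term()`, `translate_headers()`,
  `translate_instrument_output()`);
* a seeded **fixture generator** (`generate_bundle()`,
  `mutate_bundle()`) that emits byte-reproducible valid bundles and
  injects any of 34 catalogued violations with an exact expected-issue
  ledger;
* a **CLI** (`inst/cli/reportfmt`) with `validate`, `describe`,
  `recommend`, `translate` and `generate-fixture` subcommands and a
  CI-friendly exit-code contract (0 pass / 1 validation failure /
  2 usage error).

## Worked example

```r
library(reportfmt)

reg <- load_registry()
tidy(reg)[, c("id", "category", "n_fields", "n_required")]
#> # A tibble: 11 × 4
#>    id                    category        n_fields n_required
#>    <chr>                 <chr>              <int>      <int>
#>  1 csv_guidelines        cross_domain           0          0
#>  2 dataset_metadata      cross_domain           8          3
#>  3 file_level_metadata   cross_domain           6          3
#>  4 location_metadata     cross_domain           6          3
#>  5 model_archiving       cross_domain           6          6
#>  6 sample_metadata       cross_domain           7          2
#>  7 amplicon_abundance    domain_specific        2          2
#>  8 hydrologic_monitoring domain_specific        7          2
#>  9 leaf_gas_exchange     domain_specific        7          3
#> 10 soil_respiration      domain_specific        7          5
#> 11 water_soil_chemistry  domain_specific        9          5

# a synthetic bundle with two injected violations
d <- file.path(tempdir(), "demo-bundle")
generate_bundle(fixture_spec(seed = 7,
                             violations = c("COORD-BOUNDS", "DATE-FORMAT")), d)

rep <- validate_bundle(d)
glance(rep)
#> # A tibble: 1 × 7
#>   n_issues n_error n_warning n_info n_files n_schemas pass
#>      <int>   <int>     <int>  <int>   <int>     <int> <lgl>
#> 1        3       3         0      0      12        11 FALSE

writeLines(report_to_text(rep))
#> FAIL: 3 error(s), 0 warning(s), 0 info
#>   error   COORD-BOUNDS   location_metadata.csv:3 [latitude]  latitude 95.00000 outside [-90, 90]
#>   error   MIXED-TYPE     sample_metadata.csv [collection_date]  column 'collection_date' mixes incompatible value types
#>   error   DATE-FORMAT    sample_metadata.csv:3 [collection_date]  '03/05/2021' is not in YYYY-MM-DD format
```

The report reads like a compiler's output: each finding carries a stable
code, a severity, and a location (file, 1-based row counting the header
as row 1, column). The out-of-range latitude injected into the location
table and the US-style date injected into the sample table are both
found; the non-ISO date additionally makes its column mixed-type, which
is reported as its own column-level error. A bundle passes when it has
no error-severity findings.

The same run from a shell:

```sh
inst/cli/reportfmt validate demo-bundle --json report.json   # exit 1 here
inst/cli/reportfmt describe csv_guidelines
```

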