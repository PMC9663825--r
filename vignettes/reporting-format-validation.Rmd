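---
title: "Schema-driven validation of environmental (meta)data reporting formats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Schema-driven validation of environmental (meta)data reporting formats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reportfmt)
```

## The problem

Earth and environmental science datasets are archived as *bundles*: a
directory of CSV data tables plus the metadata files that make them
reusable — dataset-level citation metadata, a file-level metadata (FLMD)
table describing every file, sample and location registries, and
domain tables such as amplicon abundance matrices or sonde time series.
Community *reporting formats* prescribe how each of these pieces should
be shaped: which columns are required, how dates and coordinates are
written, which vocabularies apply. Repositories today check much of this
by hand. reportfmt encodes the family of eleven community reporting
formats as machine-readable schemas and automates the checking, so a
contributor can validate a bundle before submission and a pipeline can
gate on the result.

## The schema model

Each reporting format is one YAML file under `inst/schemas/`, declaring
an id, a category (`cross_domain` or `domain_specific`), a versioned
list of fields (name, requirement level, value type, units, vocabulary,
pattern, bounds) and a list of *table rules* (header uniqueness, one
type per column, missing-code hygiene, ISO dates). The packaged registry
holds exactly eleven schemas — six cross-domain, five domain-specific —
and `load_registry()` asserts that partition at load time.

Two schemas bend the tabular mould deliberately. The CSV guidelines
format prescribes *how any table is shaped* rather than named columns,
so it declares table rules and an empty field list; the registry
invariant is therefore "at least one required field **or** at least one
table rule" per schema. The model-archiving format is decision guidance,
not a data dictionary: its fields are checklist items with a controlled
`present/absent/not_applicable` status, and `evaluate_model_checklist()`
only ever emits warnings, so archiving advice can never fail a bundle.

Field inventories are a minimal defensible core chosen for this
implementation — enough to exercise every rule type the formats
prescribe — and each schema carries a version so inventories can grow
without code changes.

## Harmonization rules

Three conventions are fixed across all formats and implemented as
primitives:

* **Dates** are exactly zero-padded `YYYY-MM-DD` naming a real calendar
  date (`check_date()`); shape violations and impossible dates are
  distinguished (`bad_pattern` vs `bad_calendar_date`). Timestamps are
  ISO 8601; a time of day without a UTC offset is accepted with a
  warning, since the formats fix the syntax but not a timezone policy.
* **Coordinates** are harmonized as `latitude`/`longitude` in decimal
  degrees with *closed* bounds of ±90 and ±180 (`check_coordinate()`).
* **Missing values** use the in-band sentinel `-9999` for numeric
  columns; the empty string and `N/A` are the documented text-missing
  convention. These are defaults, extendable per file via the FLMD
  `missing_value_codes` column, which feeds column profiling of the
  described file. Whether `-9999` may also mark missing dates is not
  fixed by the conventions; we treat the empty string as the date-missing
  marker and flag `-9999` in a date column with a warning.

## Validation semantics

`validate_table()` is total: bad data never throws, it produces coded,
located findings (`ValidationIssue`s) in a `validation_report`. Design
choices a user should know:

* Row numbers are 1-based **counting the header as row 1**, matching
  what a spreadsheet shows.
* Header matching is case-sensitive, with a case/whitespace-insensitive
  fallback that matches but warns (`HDR-FUZZY`) — harmonized names are
  the point, but the UX should be forgiving.
* Columns a schema does not declare are *info*, never errors: the
  formats are explicitly extensible with optional context. The amplicon
  schema goes further and interprets every undeclared column as a
  per-sample count column.
* Column type profiling promotes integer+decimal to decimal and
  date+datetime to datetime; any other mixture is a `MIXED-TYPE` error.
  Missing-coded cells never influence the inferred type, so a `-9999`
  in a numeric column can never cause a type error.
* Issues are sorted by (file, row, column, code); the same input always
  yields byte-identical JSON reports.

Domain formats layer namespaced rules on top (codes `AMP-`, `GAS-`,
`CHEM-`, `HYD-`): non-negative integer counts and unique feature ids for
amplicon tables; instrument tokens that must resolve in the translation
table for gas exchange; below-detection conventions for chemistry
(embedded `"<0.5"` strings are rejected with a fix-it message, because
they destroy machine readability — the flag-plus-limit encoding is
required); and per-site timestamp ordering for hydrologic series.
Non-monotonic sensor timestamps are warnings — field data legitimately
contain re-deployments — while duplicated timestamps within a site are
errors, since they usually indicate merge faults. Analyte vocabularies
are *open*: unknown analytes warn and are collected rather than
rejected, a deliberate reaction to closed regulatory vocabularies
proving too rigid for research data.

Cross-file checks (`crosscheck_bundle()`) compare the FLMD against the
files on disk (the symmetric difference maps exactly onto
`FILE-MISSING`/`FILE-UNDESCRIBED` findings) and resolve identifier
references. Reference columns are declared per schema (chemistry
`sample_id` against the sample registry, hydrologic `site_id` against
the location registry, `parent_sample` within the sample table) rather
than guessed from arbitrary column names. IGSN checking is syntactic
only — optional `IGSN:` prefix, 2–5 letter namespace, ≥4 alphanumerics,
case-insensitive with a normalization warning — because the toolkit must
work offline; resolving identifiers against the registration network is
out of scope.

## Crosswalks and translation

A crosswalk is a CSV with columns `source_standard`, `source_term`,
`target_term`, `unit_factor`, `unit_offset`, `notes`. `map_term()` is an
exact, case-sensitive lookup (an optional case-insensitive fallback
exists, off by default, because silently case-folding can merge distinct
terms). `translate_headers()` renames matched columns and applies affine
unit conversions; unit support is deliberately limited to
factor-plus-offset transforms, which cover temperature, length and
concentration scaling without an expression engine. Two source columns
mapping onto one target is a refused collision, and identity rows with
non-trivial conversions are rejected at load, which together make
translation idempotent.

The packaged crosswalks (hydrologic, water/soil chemistry) and the
ten-instrument leaf-gas-exchange translation table are **synthetic
curations** — their filenames carry `_synthetic` — assembled for this
package from well-known public instrument output conventions and
standard terminologies. They demonstrate and test the mechanism; a
deployment would substitute community-curated tables in the same layout.

## The fixture generator

`generate_bundle()` writes a complete bundle for any subset of the
eleven formats. Fixtures emulate *format structure, not scientific
signal*: dates are uniform in the configured range, coordinates uniform
in the box, amplicon counts negative binomial (size 1, mean 50),
sequences uniform over ACGT, and chemistry values folded normals. The
default scale is 20 rows per table, 5 samples and 6 locations — desk
scale by construction. Everything derives from one integer seed and
fixed-precision formatting, so the same spec yields byte-identical
files; that determinism is itself a tested property.

Every issue code marked mutable in `issue_catalogue()` has a violation
generator: `mutate_bundle()` applies a minimal deterministic edit and
returns a ledger of the issues it introduces. Some single edits
legitimately trip several rules — a non-numeric cell in a numeric
column is both a cell `TYPE-MISMATCH` and a column `MIXED-TYPE` — and
the ledger records the full expected set. The toolkit's central
acceptance property is the round trip: generate → validate (zero
issues) → mutate → validate → the diff against the pre-mutation report
equals the ledger exactly, for all 34 mutable codes.

Because fixtures carry no realistic covariance structure, passing tests
demonstrate rule coverage and bookkeeping correctness, not robustness
to the messiness of real exported instrument files (multi-line headers,
embedded units, locale-specific decimals), which the parser does not
attempt to repair.

## Numerical and degenerate-input choices

Parsing is strict RFC 4180 (comma, double-quote escaping, `\n`/`\r\n`):
ragged rows are parse errors naming the offending row, never silently
padded; empty files are parse errors, not empty documents; cells are
kept verbatim (no whitespace trimming, no type coercion, no header
repair). Unit conversions round-trip within 1e-9 relative error where
inverse mappings exist. All randomized tests and the acceptance script
run under fixed seeds; problem sizes (1000 crosswalk lookup trials, 100
idempotence tables, 60 amplicon oracle tables, 20-row fixtures) were
chosen to exercise every code path many times while keeping the whole
suite comfortably under a couple of minutes.

## Limitations

* Schemas carry the minimal core field inventories, not the complete
  community data dictionaries.
* No spreadsheet ingestion and no streaming: bundles are read whole.
* No sequence bioinformatics, no flux computation, no sensor QA/QC
  (despiking, drift correction) — the toolkit validates *reporting*,
  not science.
* JSON-LD export covers the schema.org Dataset profile for populated
  fields only; repository-specific dissemination formats are documented
  mappings, not emitted artifacts.
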