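# Guidelines-only format: it prescribes how any tabular file is shaped
# (one header row, unique column names, one type per column, ISO dates,
# -9999 numeric missing sentinel) rather than a fixed set of columns,
# so `fields` is empty and all content lives in table_rules.
id: csv_guidelines
title: CSV File Formatting Guidelines
category: cross_domain
version: "1.0.0"
applies_to: [any]
table_rules:
  - unique-column-names
  - no-mixed-type-columns
  - missing-code-numeric
  - iso-date-format
fields: []
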