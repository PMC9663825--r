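id: file_level_metadata
title: File-Level Metadata
category: cross_domain
version: "1.0.0"
applies_to: [any]
table_rules: [unique-column-names]
fields:
  - name: file_name
    requirement: required
    value_type: identifier
    description: Exact name of a file in the dataset bundle; unique within the table.
  - name: file_description
    requirement: required
    value_type: text
    description: What the file contains and how it was produced.
  - name: file_format
    requirement: required
    value_type: text
    description: File format token, e.g. csv, fasta, json.
  - name: column_or_row_name_position
    requirement: optional
    value_type: integer
    description: 1-based line holding column (or row) names, when not the first.
  - name: missing_value_codes
    requirement: optional
    value_type: text
    description: Semicolon-separated in-band codes marking missing values in this file.
  - name: notes
    requirement: optional
    value_type: text
    description: Anything else a reuser should know about the file.
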