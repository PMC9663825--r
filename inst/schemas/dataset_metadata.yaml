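id: dataset_metadata
title: Dataset Metadata
category: cross_domain
version: "1.0.0"
applies_to: [any]
table_rules: []
fields:
  - name: title
    requirement: required
    value_type: text
    description: >
      Descriptive dataset title; long enough to convey topic, location and
      time period for citation and discovery.
  - name: abstract
    requirement: required
    value_type: text
    description: Prose summary of what the dataset contains and why it was collected.
  - name: creators
    requirement: required
    value_type: text
    description: >
      One or more dataset creators (name; optional affiliation and ORCID-style
      identifier), in citation order.
  - name: keywords
    requirement: optional
    value_type: text
    description: Free keywords aiding discovery.
  - name: temporal_coverage_start
    requirement: optional
    value_type: date
    description: First date covered by the data (YYYY-MM-DD).
  - name: temporal_coverage_end
    requirement: optional
    value_type: date
    description: Last date covered by the data (YYYY-MM-DD).
  - name: funding
    requirement: optional
    value_type: text
    description: Funding organization or award text.
  - name: related_identifiers
    requirement: optional
    value_type: text
    description: DOIs or other identifiers of related datasets and papers.
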