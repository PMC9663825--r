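id: sample_metadata
title: Sample IDs and Metadata
category: cross_domain
version: "1.0.0"
applies_to: [any]
table_rules: [unique-column-names, no-mixed-type-columns, iso-date-format]
fields:
  - name: sample_id
    requirement: required
    value_type: identifier
    description: >
      Persistent sample identifier, ideally an IGSN (International Generic
      Sample Number); unique within the table.
  - name: sample_name
    requirement: required
    value_type: text
    description: Human-readable sample name as used in the field or lab.
  - name: material
    requirement: optional
    value_type: text
    description: Material sampled (soil, water, sediment, plant tissue, ...).
  - name: collection_date
    requirement: optional
    value_type: date
    description: Date of collection (YYYY-MM-DD).
  - name: latitude
    requirement: optional
    value_type: latitude
    units: decimal degrees
    description: Collection latitude, decimal degrees, -90 to 90.
  - name: longitude
    requirement: optional
    value_type: longitude
    units: decimal degrees
    description: Collection longitude, decimal degrees, -180 to 180.
  - name: parent_sample
    requirement: optional
    value_type: identifier
    description: Identifier of the parent sample this one was subsampled from.
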