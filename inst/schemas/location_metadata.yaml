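id: location_metadata
title: Location Metadata
category: cross_domain
version: "1.0.0"
applies_to: [any]
table_rules: [unique-column-names, no-mixed-type-columns]
fields:
  - name: location_id
    requirement: required
    value_type: identifier
    description: Stable identifier for the research location; unique within the table.
  - name: location_name
    requirement: optional
    value_type: text
    description: Human-readable place name.
  - name: latitude
    requirement: required
    value_type: latitude
    units: decimal degrees
    description: Latitude in decimal degrees, -90 to 90 inclusive.
  - name: longitude
    requirement: required
    value_type: longitude
    units: decimal degrees
    description: Longitude in decimal degrees, -180 to 180 inclusive.
  - name: elevation_m
    requirement: optional
    value_type: decimal
    units: m
    bounds: [-11000, 9000]
    description: Elevation above mean sea level in metres.
  - name: location_description
    requirement: optional
    value_type: text
    description: Setting, access, and anything needed to relocate the site.
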