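# Sonde-based hydrologic time series. Extra columns beyond those declared
# are accepted as additional sonde variables (info, never error).
# Timestamps should be monotone per site (violations warn: re-deployments
# happen); duplicated timestamps within a site are errors (merge faults).
id: hydrologic_monitoring
title: Water Level and Sonde-Based Hydrologic Monitoring
category: domain_specific
version: "1.0.0"
applies_to: [hydrologic_monitoring]
table_rules: [unique-column-names, no-mixed-type-columns]
fields:
  - name: datetime
    requirement: required
    value_type: datetime
    description: Observation time, ISO 8601; offset recommended.
  - name: site_id
    requirement: required
    value_type: identifier
    description: Monitoring site / sensor deployment identifier.
  - name: water_level
    requirement: optional
    value_type: decimal
    units: m
    description: Water level or stage; missing coded -9999.
  - name: water_temperature
    requirement: optional
    value_type: decimal
    units: deg C
    bounds: [-5, 50]
    description: Water temperature.
  - name: ph
    requirement: optional
    value_type: decimal
    units: pH units
    bounds: [0, 14]
    description: pH.
  - name: specific_conductance
    requirement: optional
    value_type: decimal
    units: uS/cm
    bounds: [0, 200000]
    description: Specific conductance at 25 deg C.
  - name: dissolved_oxygen
    requirement: optional
    value_type: decimal
    units: mg/L
    bounds: [0, 30]
    description: Dissolved oxygen concentration.
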