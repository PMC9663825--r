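# Chamber-based soil-atmosphere gas flux series. Multi-gas and radiocarbon
# measurements share one table and are distinguished by gas_species.
id: soil_respiration
title: Soil Respiration
category: domain_specific
version: "1.0.0"
applies_to: [soil_respiration]
table_rules: [unique-column-names, no-mixed-type-columns]
fields:
  - name: timestamp
    requirement: required
    value_type: datetime
    description: Measurement time, ISO 8601 (date, or date + time, offset optional).
  - name: chamber_id
    requirement: required
    value_type: identifier
    description: Chamber or collar identifier.
  - name: gas_species
    requirement: required
    value_type: controlled
    vocabulary: [CO2, CH4, N2O, 14C]
    description: Gas species of the flux; 14C flags radiocarbon measurements.
  - name: flux
    requirement: required
    value_type: decimal
    description: Soil-to-atmosphere flux; missing values coded -9999.
  - name: flux_units
    requirement: required
    value_type: text
    description: Units of the flux column, canonical umol m-2 s-1.
  - name: soil_temperature
    requirement: optional
    value_type: decimal
    units: deg C
    bounds: [-40, 60]
    description: Soil temperature covariate.
  - name: soil_moisture
    requirement: optional
    value_type: decimal
    units: percent volumetric
    bounds: [0, 100]
    description: Volumetric soil moisture covariate.
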