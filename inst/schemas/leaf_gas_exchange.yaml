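id: leaf_gas_exchange
title: Leaf-Level Gas Exchange
category: domain_specific
version: "1.0.0"
applies_to: [leaf_gas_exchange]
table_rules: [unique-column-names, no-mixed-type-columns]
fields:
  - name: instrument
    requirement: required
    value_type: text
    description: >
      Instrument token (e.g. li6800); must resolve in the packaged
      instrument translation table.
  - name: raw_or_processed
    requirement: required
    value_type: controlled
    vocabulary: [raw, processed]
    description: Whether rows are raw instrument logs or processed values.
  - name: net_assimilation
    requirement: required
    value_type: decimal
    units: umol CO2 m-2 s-1
    description: Net CO2 assimilation rate (A).
  - name: stomatal_conductance
    requirement: optional
    value_type: decimal
    units: mol H2O m-2 s-1
    bounds: [0, 5]
    description: Stomatal conductance to water vapour (gsw).
  - name: intercellular_co2
    requirement: optional
    value_type: decimal
    units: umol mol-1
    bounds: [0, 3000]
    description: Intercellular CO2 mole fraction (Ci).
  - name: leaf_temperature
    requirement: optional
    value_type: decimal
    units: deg C
    bounds: [-10, 60]
    description: Leaf temperature during the measurement.
  - name: par
    requirement: optional
    value_type: decimal
    units: umol m-2 s-1
    bounds: [0, 3000]
    description: Photosynthetically active radiation incident on the leaf.
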