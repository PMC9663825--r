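# Sample-based water/soil/sediment chemistry. The analyte vocabulary is
# deliberately OPEN (vocabulary_open): unknown analytes warn, never error,
# because closed regulatory vocabularies proved too rigid for research
# data. Below-detection results use below_detection + detection_limit, not
# "<x" strings inside the numeric value column (embedded "<" is flagged).
id: water_soil_chemistry
title: Sample-Based Water and Soil Chemistry
category: domain_specific
version: "1.0.0"
applies_to: [water_soil_chemistry]
table_rules: [unique-column-names, no-mixed-type-columns]
fields:
  - name: sample_id
    requirement: required
    value_type: identifier
    description: Identifier of the physical sample measured; may reference sample metadata.
  - name: igsn
    requirement: optional
    value_type: identifier
    description: IGSN of the sample, when registered; checked syntactically.
  - name: analyte
    requirement: required
    value_type: controlled
    vocabulary_open: true
    vocabulary:
      - nitrate
      - nitrite
      - ammonium
      - sulfate
      - chloride
      - phosphate
      - dissolved_organic_carbon
      - total_nitrogen
      - calcium
      - magnesium
      - potassium
      - sodium
      - iron
      - manganese
      - ph
      - specific_conductance
    description: Measured analyte; novel terms are accepted with a warning.
  - name: value
    requirement: required
    value_type: decimal
    description: Measured value; missing coded -9999.
  - name: units
    requirement: required
    value_type: text
    description: Units of the value, e.g. mg/L, ug/L, pH units.
  - name: method
    requirement: optional
    value_type: text
    description: Analytical method description or reference.
  - name: below_detection
    requirement: optional
    value_type: controlled
    vocabulary: ["TRUE", "FALSE"]
    description: TRUE when the result is below the detection limit.
  - name: detection_limit
    requirement: optional
    value_type: decimal
    description: Reported detection limit, same units as value.
  - name: matrix
    requirement: required
    value_type: controlled
    vocabulary: [water, soil, sediment]
    description: Sample matrix.
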