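# Checklist-style format: each field is one archiving decision item with a
# controlled status rather than a data column. Evaluated advisorily
# (warnings only) by evaluate_model_checklist().
id: model_archiving
title: Terrestrial Model Data Archiving Guidelines
category: cross_domain
version: "1.0.0"
applies_to: [model_output]
table_rules: []
fields:
  - name: code_reference
    requirement: required
    value_type: controlled
    vocabulary: [present, absent, not_applicable]
    description: Reference to the exact model code version (repository tag, DOI).
  - name: inputs
    requirement: required
    value_type: controlled
    vocabulary: [present, absent, not_applicable]
    description: Model inputs and forcing data, or references to their archives.
  - name: configuration
    requirement: required
    value_type: controlled
    vocabulary: [present, absent, not_applicable]
    description: Parameter files, namelists, and run configuration.
  - name: outputs
    requirement: required
    value_type: controlled
    vocabulary: [present, absent, not_applicable]
    description: Model outputs selected for long-term archiving.
  - name: postprocessing_scripts
    requirement: required
    value_type: controlled
    vocabulary: [present, absent, not_applicable]
    description: Scripts that turn raw outputs into published figures/tables.
  - name: documentation
    requirement: required
    value_type: controlled
    vocabulary: [present, absent, not_applicable]
    description: Description of the simulation experiment and how to rerun it.
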