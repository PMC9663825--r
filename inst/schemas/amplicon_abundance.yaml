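# Amplicon (marker-gene) feature abundance table. Beyond the two declared
# columns, every additional column is interpreted as a per-sample count
# column and must hold non-negative integers (enforced by the domain rule
# layer, codes AMP-*). Sequencing and bioinformatic processing metadata
# travel in a companion key-value table with a `block` column.
id: amplicon_abundance
title: Amplicon Abundance Tables
category: domain_specific
version: "1.0.0"
applies_to: [amplicon]
table_rules: [unique-column-names]
extra_columns: sample_counts
fields:
  - name: feature_id
    requirement: required
    value_type: identifier
    description: ASV/OTU feature identifier; unique within the table.
  - name: representative_sequence
    requirement: required
    value_type: text
    pattern: "^[ACGTURYSWKMBDHVN]+$"
    description: >
      Representative DNA sequence for the feature. Strict alphabet is
      A/C/G/T/N; other IUPAC ambiguity codes are tolerated with a warning.
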