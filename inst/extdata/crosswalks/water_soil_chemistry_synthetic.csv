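source_standard,source_term,target_term,unit_factor,unit_offset,notes
wqx,MonitoringLocationIdentifier,sample_id,,,
wqx,CharacteristicName,analyte,,,
wqx,ResultMeasureValue,value,,,
wqx,ResultMeasure/MeasureUnitCode,units,,,
wqx,ResultDetectionConditionText,below_detection,,,
wqx,DetectionQuantitationLimitMeasure/MeasureValue,detection_limit,,,
wqx,ActivityMediaName,matrix,,,
earthchem_like,SAMPLE ID,sample_id,,,
earthchem_like,ANALYTE,analyte,,,
earthchem_like,VALUE,value,,,
earthchem_like,UNITS,units,,,
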