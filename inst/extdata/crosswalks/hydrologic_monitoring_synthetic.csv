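source_standard,source_term,target_term,unit_factor,unit_offset,notes
wqx,ValueDateTime,datetime,,,date-time reported under a different name
wqx,MonitoringLocationIdentifier,site_id,,,
wqx,"Temperature, water",water_temperature,,,
odm2,LocalDateTime,datetime,,,
odm2,SamplingFeatureCode,site_id,,,
odm2,waterLevel,water_level,,,
cf,water_surface_height_above_reference_datum,water_level,,,
cf,sea_water_ph_reported_on_total_scale,ph,,,
usgs_nwis,00065,water_level,0.3048,0,gage height reported in feet
usgs_nwis,00010,water_temperature,,,
usgs_nwis,00400,ph,,,
usgs_nwis,00095,specific_conductance,,,
usgs_nwis,00300,dissolved_oxygen,,,
field_sheet,temp_F,water_temperature,0.5555555556,-17.7777777778,Fahrenheit to Celsius
field_sheet,stage_cm,water_level,0.01,0,centimetres to metres
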