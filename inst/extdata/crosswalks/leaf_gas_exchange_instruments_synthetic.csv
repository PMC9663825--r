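source_standard,source_term,target_term,unit_factor,unit_offset,notes
li6400,Photo,net_assimilation,,,
li6400,Cond,stomatal_conductance,,,
li6400,Ci,intercellular_co2,,,
li6400,Tleaf,leaf_temperature,,,
li6400,PARi,par,,,
li6800,A,net_assimilation,,,
li6800,gsw,stomatal_conductance,,,
li6800,Ci,intercellular_co2,,,
li6800,Tleaf,leaf_temperature,,,
li6800,Qin,par,,,
ciras2,A,net_assimilation,,,
ciras2,gs,stomatal_conductance,0.001,0,mmol to mol
ciras2,Ci,intercellular_co2,,,
ciras2,Tleaf,leaf_temperature,,,
ciras2,PARi,par,,,
ciras3,A,net_assimilation,,,
ciras3,gs,stomatal_conductance,0.001,0,mmol to mol
ciras3,Ci,intercellular_co2,,,
ciras3,Tleaf,leaf_temperature,,,
ciras3,PARi,par,,,
targas1,A,net_assimilation,,,
targas1,gs,stomatal_conductance,0.001,0,mmol to mol
targas1,Ci,intercellular_co2,,,
targas1,Tl,leaf_temperature,,,
targas1,Q,par,,,
gfs3000,A,net_assimilation,,,
gfs3000,GH2O,stomatal_conductance,0.001,0,mmol to mol
gfs3000,ci,intercellular_co2,,,
gfs3000,Tleaf,leaf_temperature,,,
gfs3000,PARtop,par,,,
lcpro_t,A,net_assimilation,,,
lcpro_t,gs,stomatal_conductance,,,
lcpro_t,Ci,intercellular_co2,,,
lcpro_t,Tleaf,leaf_temperature,,,
lcpro_t,Q,par,,,
lci,A,net_assimilation,,,
lci,gs,stomatal_conductance,,,
lci,Ci,intercellular_co2,,,
lci,Tlf,leaf_temperature,,,
lci,Q,par,,,
ci340,Pn,net_assimilation,,,
ci340,gs,stomatal_conductance,,,
ci340,Ci,intercellular_co2,,,
ci340,Tl,leaf_temperature,,,
ci340,PAR,par,,,
os_ptm48,Pn,net_assimilation,,,
os_ptm48,gs,stomatal_conductance,0.001,0,mmol to mol
os_ptm48,Ci,intercellular_co2,,,
os_ptm48,Tleaf,leaf_temperature,,,
os_ptm48,PAR,par,,,
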