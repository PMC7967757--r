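section,item,concept,printed,digits,method,tol,known_deviation,note
cost,raw_materials,I,1.2,1,round,,FALSE,
cost,raw_materials,II,1.3,1,round,,FALSE,
cost,raw_materials,III,1.2,1,round,,FALSE,
cost,raw_materials,IV,1.4,1,round,,FALSE,
cost,utilities,I,0.0,1,round,,FALSE,no purchased utilities
cost,utilities,II,0.1,1,round,,FALSE,
cost,utilities,III,0.2,1,round,,FALSE,
cost,utilities,IV,0.3,1,round,,FALSE,
cost,labour,I,0.2,1,round,,FALSE,
cost,labour,II,0.1,1,round,,FALSE,
cost,labour,III,0.3,1,round,,FALSE,
cost,labour,IV,0.5,1,round,,FALSE,
cost,logistics,I,0.1,1,round,,FALSE,
cost,logistics,II,0.0,1,round,,FALSE,no residue transported
cost,logistics,III,0.0,1,round,,FALSE,no residue transported
cost,logistics,IV,0.01,2,round,,FALSE,
cost,maintenance,I,0.3,1,round,,FALSE,
cost,maintenance,II,0.03,2,round,,FALSE,
cost,maintenance,III,0.2,1,round,,FALSE,
cost,maintenance,IV,0.3,1,round,,FALSE,
cost,depreciation,I,0.7,1,round,,FALSE,
cost,depreciation,II,0.1,1,round,,FALSE,
cost,depreciation,III,0.5,1,round,,FALSE,
cost,depreciation,IV,0.8,1,round,,FALSE,
cost,other_indirect,I,0.1,1,round,,FALSE,
cost,other_indirect,II,0.01,2,round,,FALSE,
cost,other_indirect,III,0.1,1,round,,FALSE,
cost,other_indirect,IV,0.1,1,round,,FALSE,
cost,mineral_fertilisers,I,0.0,1,round,,FALSE,digestate covers demand
cost,mineral_fertilisers,II,0.6,1,round,,FALSE,
cost,mineral_fertilisers,III,0.6,1,round,,FALSE,
cost,mineral_fertilisers,IV,0.5,1,round,,FALSE,
cost,total,I,2.5,1,round,,FALSE,
cost,total,II,2.2,1,round,,FALSE,
cost,total,III,3.0,1,round,,FALSE,
cost,total,IV,3.9,1,round,,TRUE,recomputes 3.8: sum of unrounded lines
revenue,oil,I,0.0,1,round,,FALSE,
revenue,oil,II,0.0,1,round,,FALSE,
revenue,oil,III,2.3,1,round,,TRUE,recomputes 2.2 from 187 kg/tRM x 1200 USD/t
revenue,oil,IV,2.9,1,round,,FALSE,
revenue,protein,I,0.0,1,round,,FALSE,
revenue,protein,II,0.0,1,round,,FALSE,
revenue,protein,III,1.7,1,round,,FALSE,
revenue,protein,IV,6.6,1,round,,TRUE,recomputes 6.7 from 171 kg/tRM x 3900 USD/t
revenue,meal,I,0.0,1,round,,FALSE,
revenue,meal,II,2.4,1,round,,FALSE,
revenue,meal,III,2.2,1,round,,TRUE,recomputes 2.1 from 158 kg/tRM x 1350 USD/t
revenue,meal,IV,0.0,1,round,,FALSE,
revenue,energy,I,1.2,1,round,,FALSE,
revenue,energy,II,0.0,1,round,,FALSE,
revenue,energy,III,0.0,1,round,,FALSE,
revenue,energy,IV,0.2,1,round,,FALSE,
revenue,total,I,1.2,1,round,,FALSE,
revenue,total,II,2.4,1,round,,FALSE,
revenue,total,III,6.2,1,round,,TRUE,recomputes 6.1: follows the oil and meal lines
revenue,total,IV,9.7,1,round,,FALSE,
profit,profit,I,-1.3,1,round,,FALSE,
profit,profit,II,0.2,1,round,,FALSE,
profit,profit,III,3.1,1,round,,FALSE,
profit,profit,IV,5.8,1,round,,TRUE,recomputes 5.9: follows the protein line
roi,roi_pct,I,-13,0,round,,FALSE,
roi,roi_pct,II,21,0,round,,FALSE,
roi,roi_pct,III,42,0,round,,FALSE,
roi,roi_pct,IV,51,0,round,,TRUE,recomputes 52: follows the protein line
energy,e_bm,I,9992,,rel,0.005,FALSE,(1562+1213) kWh x 3.6
energy,e_bm,IV,1299,,rel,0.005,FALSE,(203+158) kWh x 3.6
energy,e_input,I,2548,,rel,0.005,FALSE,
energy,ratio,I,3.9,1,round,,FALSE,
energy,ratio,IV,1.0,1,round,,FALSE,
energy,processing,I,82,,rel,0.005,FALSE,
energy,processing,II,326,,rel,0.005,FALSE,
energy,processing,III,377,,rel,0.005,FALSE,
energy,processing,IV,678,,rel,0.005,FALSE,
energy,transport,I,82.1,,rel,0.005,FALSE,
energy,transport,II,82.1,,rel,0.005,FALSE,
energy,transport,III,82.1,,rel,0.005,FALSE,
energy,transport,IV,82.1,,rel,0.005,FALSE,
energy,biogas_plant,I,2196,,rel,0.005,FALSE,plant self-consumption
energy,biogas_plant,IV,293,,rel,0.005,FALSE,plant self-consumption
energy,electricity_generated,I,1213,,rel,0.005,FALSE,
energy,electricity_generated,IV,158,,rel,0.005,FALSE,
energy,electricity_useful,I,1042,,rel,0.005,FALSE,
energy,electricity_useful,II,-41,,rel,0.005,FALSE,net purchase
energy,electricity_useful,III,-51,,rel,0.005,FALSE,net purchase
energy,electricity_useful,IV,66,,rel,0.005,FALSE,
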