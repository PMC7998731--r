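# Example study configuration: supinoxin in the rat.
compound: supinoxin
molecular_weight: 441.465   # g/mol
logP: 2.7                   # octanol:water
pKa: 1.5
compound_type: monoprotic acid
fu_plasma: 0.0363           # equilibrium dialysis, 1 ug/mL
fu_mic: 0.623               # microsomal incubation, 0.5 mg protein/mL
blood_plasma_ratio: 1
dose: 5                     # mg/kg
route: po
body_weight_ref: 0.25       # kg
seed: 0
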