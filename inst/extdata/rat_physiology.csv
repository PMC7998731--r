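compartment,volume_mL_kg,flow_mL_h_kg
venous_blood,36.0,NA
arterial_blood,18.0,NA
lung,4.0,17760
brain,6.8,355
heart,3.2,870
kidneys,9.2,2504
muscles,488,4937
adipose,40.0,1243
skin,190,1030
bone,73,2167
testes,10.0,89
spleen,2.4,210
gut,40.0,2726
liver,41.0,544
rest,38.4,1085
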