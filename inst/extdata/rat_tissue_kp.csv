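tissue,auc_0_24_ug_h_mL,kp,volume_mL_kg,kp_x_volume_mL_kg,provenance
plasma,5.108,1.00,31.2,31.2,measured
brain,4.349,0.85,6.80,5.80,measured
liver,24.31,4.76,41.0,196,measured
kidneys,11.13,2.18,9.20,20.0,measured
testes,5.370,1.05,10.0,10.5,measured
heart,3.551,0.70,3.20,2.20,measured
lungs,5.523,1.08,4.00,4.30,measured
spleen,3.314,0.65,2.40,1.60,measured
gut,25.31,4.96,40.0,198,measured
muscles,6.134,1.20,488,586,measured
adipose,110.6,21.7,40.0,866,measured
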