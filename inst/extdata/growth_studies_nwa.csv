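study,L_inf_cm,k_per_year
Avens_2015_sex_averaged,112.35,0.0440
BraunMcNeill_2008,106.90,0.0521
Foster_1994,96.74,0.0637
Frazer_1987,94.70,0.1150
Henwood_1987,110.00,0.0313
Schmid_1995_all_data,96.08,0.0586
Schmid_1995_interval_ge_1yr,96.10,0.0573
SEFSC_2001,99.70,0.0530
Vaughan_1981,102.98,0.0759
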