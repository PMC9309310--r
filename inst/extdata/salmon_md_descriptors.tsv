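pigment_id	opsin_class	torsion15	angle3	torsion3	torsion12	rmsf_auc
Rh2-1	rh2	3.64	NA	NA	NA	0.79
Rh2-2	rh2	3.06	NA	NA	NA	0.76
Rh2-3	rh2	0.41	NA	NA	NA	1.12
Rh2-4	rh2	0.84	NA	NA	NA	1.1
Sws2	sws2	NA	132.33	2.14	-5.1	NA
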