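pigment_id	opsin_class	lambda_max_nm
Sws1	sws1	360
Sws2	sws2	420
Rh2-1	rh2	472
Rh2-2	rh2	476
Rh2-3	rh2	511
Rh2-4	rh2	506
Lws1	lws	560
Lws2	lws	553
Lws3	lws	546
Lws4	lws	553
Rh1	rh1	509
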