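gene	dd225	dd320	dd410	dd800
rh1-1	1	1	10	30740
sws1-1	0	1	3	698
sws2	0	0	1	351
rh2-1	9	4	20	211
rh2-2	3	6	22	219
rh2-3	0	0	10	754
rh2-4	0	1	4	513
lws1	0	1	0	2
lws2	0	0	0	1240
lws3	1	0	0	8
lws4	0	0	2	304
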