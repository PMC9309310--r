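class	site	ancestral	substituted	delta_nm	citation
lws	164	S	A	-7	five-sites rule (LWS mutagenesis literature)
lws	181	H	Y	-28	five-sites rule (LWS mutagenesis literature)
lws	261	Y	F	-8	five-sites rule (LWS mutagenesis literature)
lws	269	T	A	-15	five-sites rule (LWS mutagenesis literature)
lws	292	A	S	-27	five-sites rule (LWS mutagenesis literature)
rh1	83	D	N	-6	rod opsin mutagenesis literature
rh1	122	E	Q	-15	rod opsin mutagenesis literature
rh1	164	A	S	2	rod opsin mutagenesis literature
rh1	261	F	Y	10	rod opsin mutagenesis literature
rh1	269	A	T	14	rod opsin mutagenesis literature
rh1	292	A	S	-10	rod opsin mutagenesis literature
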