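region	start	end
tm1	34	64
tm2	71	100
tm3	106	139
tm4	150	172
tm5	200	225
tm6	246	277
tm7	285	309
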