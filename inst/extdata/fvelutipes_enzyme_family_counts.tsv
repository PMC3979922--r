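group	family	count
AA	AA1	3
AA	AA2	3
AA	AA3	23
AA	AA4	0
AA	AA5	6
AA	AA6	2
AA	AA7	15
AA	AA8	1
AA	AA9	16
AA	AA10	0
CAZyme	GH	193
CAZyme	GT	85
CAZyme	PL	23
CAZyme	CE	91
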