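row	label	quantity	value	n
A	Based on	Valid groups	134	1176
B	Goodness of fit	R^2^	0.998	1111
C	Deviation	Average	6.09	1111
D	Deviation	Standard	8.24	1111
E	K-fold cv	K	10	1060
F	Goodness of fit	Q^2^	0.9975	1060
G	Deviation	Average (cv)	6.85	1060
H	Deviation	Standard (cv)	9.19	1060
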