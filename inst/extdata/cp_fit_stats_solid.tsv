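row	label	quantity	value	n
A	Based on	Valid groups	126	802
B	Goodness of fit	*r* ^2^	0.9915	734
C	Deviation	Average	9.36	734
D	Deviation	Standard	12.21	734
E	K-fold cv	K	10	663
F	Goodness of fit	*q* ^2^	0.9874	663
G	Deviation	Average (cv)	11.1	663
H	Deviation	Standard (cv)	14.23	663
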