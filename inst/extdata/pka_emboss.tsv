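group	pka	polarity
R	12.5	base
K	10.8	base
Y	10.1	acid
C	8.5	acid
H	6.5	base
E	4.1	acid
D	3.9	acid
nterm	8.6	base
cterm	3.6	acid
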