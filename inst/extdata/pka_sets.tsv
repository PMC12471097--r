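# Ionizable-group pKa sets for Henderson-Hasselbalch net charge and pI.
# Two sets are shipped: "pi" (EMBOSS-style, His 6.5) reproduces the published
# theoretical pI column; "charge" (identical except His 6.0) reproduces the
# published pH-7 net charges. group is a residue code or nterm/cterm;
# polarity is acid (deprotonates to -1) or base (protonates to +1).
set	group	pka	polarity
pi	nterm	8.6	base
pi	cterm	3.6	acid
pi	C	8.5	acid
pi	D	3.9	acid
pi	E	4.1	acid
pi	H	6.5	base
pi	K	10.8	base
pi	R	12.5	base
pi	Y	10.1	acid
charge	nterm	8.6	base
charge	cterm	3.6	acid
charge	C	8.5	acid
charge	D	3.9	acid
charge	E	4.1	acid
charge	H	6.0	base
charge	K	10.8	base
charge	R	12.5	base
charge	Y	10.1	acid
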