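sample_id	gene	chrom	gender	f_x	m_x1	m_x2	haplotype	results
Embryo1	SH2D1A	chrX	F	0	0	0	-	-
Embryo2	SH2D1A	chrX	M	0	137	1	M(X1)	N
Embryo3	SH2D1A	chrX	F	0	0	0	-	-
Embryo4	SH2D1A	chrX	F	0	63	0	M(X1)	N
Embryo5	SH2D1A	chrX	F	1	95	0	M(X1)	N
Embryo6	SH2D1A	chrX	F	0	0	0	-	-
Embryo7	SH2D1A	chrX	F	2	96	1	M(X1)	N
Embryo8	SH2D1A	chrX	F	1	69	1	M(X1)	N
Embryo9	SH2D1A	chrX	F	0	0	0	-	-
Embryo10	SH2D1A	chrX	F	2	26	0	M(X1)	N
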