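SNP	A1	A2	freq	b	se	p	N
rs1	A	G	0.3	0.62	0.1	5.64632e-10	1000
rs2	C	T	0.12	0.45	0.07	1.28809e-10	1000
rs3	G	A	0.41	-0.38	0.06	2.3992e-10	1000
rs4	T	C	0.25	0.11	0.09	0.221624	1000
rs5	A	C	0.08	0.21	0.12	0.0801183	1000
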