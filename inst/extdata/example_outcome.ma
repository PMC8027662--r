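SNP	A1	A2	freq	b	se	p	N
rs1	A	G	0.31	0.055	0.009	9.89398e-10	10000
rs2	C	T	0.13	0.041	0.0065	2.83227e-10	10000
rs3	G	A	0.4	-0.012	0.0098	0.220768	10000
rs4	T	C	0.24	0.003	0.01	0.764177	10000
rs5	A	C	0.09	0.018	0.011	0.101764	10000
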