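name	pattern	universe_hits	gc_induced_hits	gc_repressed_hits	lf_induced_hits	lf_repressed_hits
ABRE	(C/G/T)ACGTG(G/T)(A/C)	3178	382	49	188	57
CE3	ACGCGTGTC	24	7	0	6	1
DRE/CRT	(A/G)CCGAC	2748	137	56	85	58
CBF	(A/G)(C/T)CGAC	6236	284	131	215	133
LTRE	CCGAC	5062	229	106	162	119
MYB	(C/T)AAC(G/T)G	9108	313	213	246	195
MYC	CACATG	4909	180	138	165	118
SORLIP1AT	GCCAC	6609	321	152	189	136
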