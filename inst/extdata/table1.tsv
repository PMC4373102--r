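annotation	level	total	sg1	sg2	sg3	sg4
stage	Ta	45	16	14	5	10
stage	T1	25	2	5	9	9
stage	MI	27	0	1	10	16
stage	Tx	1	0	1	0	0
grade	1	19	11	5	1	2
grade	2	32	7	11	4	10
grade	3	47	0	5	19	23
tp53	mut	29	0	4	11	14
tp53	wt	69	18	17	13	21
fgfr3	mut	34	12	11	1	10
fgfr3	wt	64	6	10	23	25
lund_subtype	UrobasalA	44	18	15	2	9
lund_subtype	UrobasalB	12	0	5	2	5
lund_subtype	GenomicallyUnstable	29	0	0	17	12
lund_subtype	SCC-like	13	0	1	3	9
epitype	A	17	9	6	0	2
epitype	B	9	1	1	0	7
epitype	C	17	0	1	11	5
epitype	D	7	0	1	0	6
epitype	NA	48	8	12	13	15
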