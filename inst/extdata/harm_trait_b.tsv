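SNP	CHR	BP	A1	A2	Z	P
rsb01	1	100000	A	G	0.9	0.3681
rsb02	1	200000	T	C	1.7	0.0891
rsb03	1	300000	A	T	0.6	0.5485
rsb04	2	100000	G	A	-1.2	0.2301
rsb05	2	200000	C	T	-0.3	0.7642
rsb06	2	300000	C	G	1.4	0.1615
rsb07	3	100000	T	G	0.8	0.4237
rsb08	3	200000	A	C	2.2	0.0278
rsb09	3	300000	G	T	-1.1	0.2713
rsb10	4	100000	C	T	0.4	0.6892
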