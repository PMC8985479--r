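SNP	CHR	BP	A1	A2	Z	P
rs001	1	1000000	A	G	1.2	0.2301
rs002	1	2000000	C	T	-0.5	0.6171
rs003	2	1500000	I	D	0.3	0.7642
rs004	2	2500000	G	A	2.1	0.0357
rs005	3	1200000	T	C	-1.8	0.0719
rs006	3	2200000	A	C	0.9	0.3681
rs007	4	1800000	N	G	-0.2	0.8415
rs008	4	2800000	T	G	1.5	0.1336
rs009	5	1400000	C	A	-2.5	0.0124
rs010	5	2400000	G	T	0.7	0.4839
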