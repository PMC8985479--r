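SNP	CHR	BP	A1	A2	Z	P
rsa01	1	100000	A	G	0.5	0.6171
rsa02	1	200000	C	T	1.1	0.2713
rsa03	1	300000	A	T	2.0	0.0455
rsa04	2	100000	G	A	-0.8	0.4237
rsa05	2	200000	T	C	1.3	0.1936
rsa06	2	300000	C	A	-1.9	0.0574
rsa07	3	100000	G	T	0.2	0.8415
rsa08	3	200000	A	C	2.6	0.0093
rsa09	3	300000	T	G	-0.4	0.6892
rsa10	4	100000	C	T	1.0	0.3173
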