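SNP	CHR	BP	A1	A2	Z	P
wf01	1	1000000	A	G	3.29052673149189	0.001
wf02	1	1100000	A	G	2.5758293035489	0.01
wf03	1	1200000	A	G	2.32634787404084	0.02
wf04	1	1300000	A	G	1.95996398454005	0.05
wf05	1	1400000	A	G	1.64485362695147	0.1
wf06	1	1500000	A	G	1.2815515655446	0.2
wf07	1	1600000	A	G	1.03643338949379	0.3
wf08	1	1700000	A	G	0.755415026360469	0.45
wf09	1	1800000	A	G	0.385320466407568	0.7
wf10	1	1900000	A	G	0.125661346855074	0.9
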