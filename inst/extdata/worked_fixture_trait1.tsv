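SNP	CHR	BP	A1	A2	Z	P
wf01	1	1000000	A	G	3.29052673149189	0.001
wf02	1	1100000	A	G	2.32634787404084	0.02
wf03	1	1200000	A	G	1.03643338949379	0.3
wf04	1	1300000	A	G	0.674489750196082	0.5
wf05	1	1400000	A	G	0.125661346855074	0.9
wf06	1	1500000	A	G	0.93458929107348	0.35
wf07	1	1600000	A	G	0.755415026360469	0.45
wf08	1	1700000	A	G	0.597760126042478	0.55
wf09	1	1800000	A	G	0.453762190169879	0.65
wf10	1	1900000	A	G	0.318639363964375	0.75
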