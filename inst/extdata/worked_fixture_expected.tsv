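snp_id	cfdr_1given2	cfdr_2given1	conjfdr
wf01	0.001	0.001	0.001
wf02	0.02	0.01	0.02
wf03	0.3	0.02	0.3
wf04	0.5	0.075	0.5
wf05	0.9	0.2	0.9
wf06	0.525	0.2	0.525
wf07	0.63	0.3	0.63
wf08	0.628571428571429	0.45	0.628571428571429
wf09	0.73125	0.7	0.73125
wf10	0.833333333333333	0.9	0.9
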