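lead_snp	chr_region	pos	conjfdr_cd	conjfdr_ibd	closest_gene	relation
rs12740041	1q31.3	197814607	2.73e-2	2.80e-2	C1orf53	Upstream
rs4957144	5p13.1	40914326	2.37e-2	2.44e-2	C7	Intronic
rs116843836	20p13	1033414	1.96e-2	9.42e-2	RSPO4	Upstream
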