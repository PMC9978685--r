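variant_id	effect_allele	other_allele	eaf	beta	se	pvalue	n	z	locus
rs1000001	T	C	0.8711758399382233	0.03656282580868503	0.01	2.558992583444288e-4	300000	3.6562825808685027	rs1000001
rs1000002	A	C	0.35352699849754576	0.042258057229474476	0.01	2.380873384405619e-5	300000	4.225805722947447	rs1000002
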