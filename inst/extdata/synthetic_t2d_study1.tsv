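variant_id	effect_allele	other_allele	eaf	beta	se	pvalue	n	z	locus
rs1000001	C	T	0.12882416006177666	-0.026013454302891988	0.01	0.009285890035413857	300000	-2.6013454302891987	rs1000001
rs1000002	A	C	0.35352699849754576	0.015396658494271485	0.01	0.12364182528032225	300000	1.5396658494271485	rs1000002
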