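variant_id	effect_allele	other_allele	eaf	beta	se	pvalue	n	z	locus
rs1000001	C	T	0.12882416006177666	0.15861439353050982	0.016	3.6404377085217354e-23	10000	9.913399595656864	CYP1A2
rs1000002	C	A	0.6464730015024542	0.14928199939545664	0.016	1.0574615870153778e-20	10000	9.33012496221604	AHR
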