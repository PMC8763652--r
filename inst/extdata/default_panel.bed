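chr_BRAF	100	421	BRAF|ex11
chr_BRAF	621	942	BRAF|ex15
chr_CDKN2A	100	421	CDKN2A|ex1
chr_CDKN2A	621	942	CDKN2A|ex2
chr_CTNNB1	100	421	CTNNB1|ex3
chr_EGFR	100	421	EGFR|ex18
chr_EGFR	621	942	EGFR|ex19
chr_EGFR	1142	1463	EGFR|ex20
chr_EGFR	1663	1984	EGFR|ex21
chr_ERBB2	100	421	ERBB2|ex20
chr_HRAS	100	421	HRAS|ex2
chr_HRAS	621	942	HRAS|ex3
chr_KEAP1	100	421	KEAP1|ex2
chr_KEAP1	621	942	KEAP1|ex3
chr_KEAP1	1142	1463	KEAP1|ex4
chr_KEAP1	1663	1984	KEAP1|ex5
chr_KEAP1	2184	2505	KEAP1|ex6
chr_KIT	100	421	KIT|ex9
chr_KIT	621	942	KIT|ex11
chr_KIT	1142	1463	KIT|ex13
chr_KIT	1663	1984	KIT|ex14
chr_KIT	2184	2505	KIT|ex17
chr_KRAS	100	421	KRAS|ex2
chr_KRAS	621	942	KRAS|ex3
chr_KRAS	1142	1463	KRAS|ex4
chr_MET	100	421	MET|ex14
chr_NFE2L2	100	421	NFE2L2|ex2
chr_NRAS	100	421	NRAS|ex2
chr_NRAS	621	942	NRAS|ex3
chr_PDGFRA	100	421	PDGFRA|ex18
chr_PIK3CA	100	421	PIK3CA|ex10
chr_PIK3CA	621	942	PIK3CA|ex21
chr_PTEN	100	421	PTEN|ex1
chr_PTEN	621	942	PTEN|ex3
chr_PTEN	1142	1463	PTEN|ex6
chr_PTEN	1663	1984	PTEN|ex7
chr_PTEN	2184	2505	PTEN|ex8
chr_SDHA	100	421	SDHA|ex2
chr_SDHA	621	942	SDHA|ex7
chr_SDHA	1142	1463	SDHA|ex13
chr_SMAD4	100	420	SMAD4|ex1
chr_SMAD4	620	940	SMAD4|ex2
chr_SMAD4	1140	1460	SMAD4|ex8
chr_SMAD4	1660	1980	SMAD4|ex9
chr_SMAD4	2180	2500	SMAD4|ex10
chr_SMAD4	2700	3020	SMAD4|ex11
chr_TP53	100	420	TP53|ex4
chr_TP53	620	940	TP53|ex5
chr_TP53	1140	1460	TP53|ex6
chr_TP53	1660	1980	TP53|ex7
chr_TP53	2180	2500	TP53|ex8
chr_TP53	2700	3020	TP53|ex9
chr_TP53	3220	3540	TP53|ex10
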