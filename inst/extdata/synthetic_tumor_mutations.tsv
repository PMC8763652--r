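patient_id	gene	n_mutations
P01	KEAP1	1
P01	TP53	1
P01	HRAS	1
P01	PIK3CA	1
P01	ERBB2	1
P01	PTEN	1
P01	SMAD4	1
P01	KIT	1
P01	NFE2L2	1
P01	CDKN2A	1
P02	KEAP1	1
P02	TP53	1
P02	PIK3CA	1
P02	ERBB2	1
P02	PTEN	1
P02	SMAD4	1
P02	KIT	1
P02	NFE2L2	1
P02	CDKN2A	1
P02	NRAS	1
P03	KEAP1	1
P03	TP53	1
P03	ERBB2	1
P03	PTEN	1
P03	SMAD4	1
P03	KIT	1
P03	NFE2L2	1
P03	CDKN2A	1
P03	NRAS	1
P03	CTNNB1	1
P04	KEAP1	1
P04	TP53	1
P04	EGFR	1
P04	PTEN	1
P04	SMAD4	1
P04	KIT	1
P04	NFE2L2	1
P04	CDKN2A	1
P04	NRAS	1
P05	KEAP1	1
P05	TP53	1
P05	EGFR	1
P05	SMAD4	1
P05	KIT	1
P05	NFE2L2	1
P05	CDKN2A	1
P05	NRAS	1
P05	CTNNB1	1
P05	KRAS	1
P05	HRAS	1
P05	PIK3CA	1
P06	KEAP1	1
P06	TP53	1
P06	EGFR	1
P06	KIT	1
P06	NFE2L2	1
P06	CDKN2A	1
P06	NRAS	1
P06	CTNNB1	1
P06	KRAS	1
P06	HRAS	1
P07	KEAP1	1
P07	TP53	1
P07	EGFR	1
P07	NFE2L2	1
P07	CDKN2A	1
P07	NRAS	1
P07	CTNNB1	1
P07	KRAS	1
P08	KEAP1	1
P08	TP53	1
P08	EGFR	1
P08	PDGFRA	1
P08	CDKN2A	1
P08	NRAS	1
P08	CTNNB1	1
P08	KRAS	1
P08	HRAS	1
P08	PIK3CA	1
P08	ERBB2	1
P09	KEAP1	1
P09	TP53	1
P09	EGFR	1
P09	PDGFRA	1
P09	NRAS	1
P09	CTNNB1	1
P09	KRAS	1
P09	HRAS	1
P09	PIK3CA	1
P09	ERBB2	1
P10	KEAP1	1
P10	TP53	1
P10	EGFR	1
P10	PDGFRA	1
P10	CTNNB1	1
P10	KRAS	1
P10	HRAS	1
P10	PIK3CA	1
P10	ERBB2	1
P10	PTEN	1
P10	SMAD4	1
P10	KIT	1
P10	NFE2L2	1
P11	KEAP1	1
P11	TP53	1
P11	EGFR	1
P11	PDGFRA	1
P11	KRAS	1
P11	HRAS	1
P11	PIK3CA	1
P11	ERBB2	1
P11	PTEN	1
P12	KEAP1	1
P12	TP53	1
P12	EGFR	1
P12	PDGFRA	1
P12	HRAS	1
P12	PIK3CA	1
P12	ERBB2	1
P12	PTEN	1
P12	SMAD4	1
P12	KIT	1
P13	KEAP1	1
P13	TP53	1
P13	EGFR	1
P13	PDGFRA	1
P13	PIK3CA	1
P13	ERBB2	1
P13	PTEN	1
P13	SMAD4	1
P13	KIT	1
P13	NFE2L2	1
P13	CDKN2A	1
P13	NRAS	1
P13	CTNNB1	1
P13	KRAS	1
P14	KEAP1	1
P14	TP53	1
P14	EGFR	1
P14	PDGFRA	1
P14	ERBB2	1
P14	PTEN	1
P14	SMAD4	1
P14	KIT	1
P14	NFE2L2	1
P14	CDKN2A	1
P14	NRAS	1
P15	KEAP1	1
P15	PDGFRA	1
P15	PTEN	1
P15	SMAD4	1
P15	KIT	1
P15	NFE2L2	1
P15	CDKN2A	1
P15	NRAS	1
P15	CTNNB1	1
P15	KRAS	1
P16	KEAP1	1
P16	PDGFRA	1
P16	SMAD4	1
P16	KIT	1
P16	NFE2L2	1
P16	CDKN2A	1
P16	NRAS	1
P16	CTNNB1	1
P16	KRAS	1
P16	HRAS	1
P16	PIK3CA	1
P16	ERBB2	1
P17	KEAP1	1
P17	PDGFRA	1
P17	KIT	1
P17	NFE2L2	1
P17	CDKN2A	1
P17	NRAS	1
P17	CTNNB1	1
P18	PDGFRA	1
P18	NFE2L2	1
P18	CDKN2A	1
P18	NRAS	1
P18	CTNNB1	1
P18	KRAS	1
P18	HRAS	1
P18	PIK3CA	1
P18	ERBB2	1
P18	PTEN	1
P19	CDKN2A	1
P19	NRAS	1
P19	CTNNB1	1
P19	KRAS	1
P19	HRAS	1
P19	PIK3CA	1
P20	NRAS	1
P20	CTNNB1	1
P20	KRAS	1
P20	HRAS	1
P20	PIK3CA	1
P20	ERBB2	1
P20	PTEN	1
P20	SMAD4	1
P20	KIT	1
P20	NFE2L2	1
P21	CTNNB1	2
P21	KRAS	2
P21	HRAS	2
P21	PIK3CA	2
P21	ERBB2	1
P21	PTEN	1
P21	SMAD4	1
P21	KIT	1
P21	NFE2L2	1
P21	CDKN2A	1
P21	NRAS	1
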