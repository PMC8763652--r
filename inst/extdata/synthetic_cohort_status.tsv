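patient_id	stage	presurgery	intraoperative	postsurgery	relapse_day	death_day	last_followup_day
P01	IIIA	positive		negative			798
P02	IIIA	positive	positive	positive	320	500	500
P03	IIIA	negative	positive				798
P04	IIIA	negative	positive	positive	226	420	420
P05	IIIA		positive	negative	400	700	700
P06	IIIA		positive				798
P07	IIIA		positive	negative			798
P08	IIIA	negative	negative	negative			798
P09	IIIB	negative	negative	negative	500		798
P10	IIIB	negative	negative	negative			798
P11	IA	positive	positive	negative	620		798
P12	IA	negative	negative	negative			798
P13	IIA	negative	positive	positive	280		798
P14	IIB	negative	positive	negative	450		798
P15	IIB	negative	positive	negative			798
P16	IIB	negative	positive	negative			798
P17	IIB	negative		negative			798
P18	IIB		negative				798
P19	IIB		negative				798
P20	IIB	negative	negative				798
P21	IIB	negative	negative	positive	160	410	410
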