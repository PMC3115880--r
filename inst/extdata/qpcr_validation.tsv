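gene	symbol	tissue	microarray	qpcr
ACTIN	Actin2/Actin8	guard_cell	none	none
ACTIN	Actin2/Actin8	leaf	none	none
AT4G20890	TUB9	guard_cell	none	none
AT4G20890	TUB9	leaf	none	none
AT2G40000	HSPRO2	guard_cell	none	none
AT2G40000	HSPRO2	leaf	none	none
AT5G57050	ABI2	guard_cell	induced	induced
AT5G57050	ABI2	leaf	induced	induced
AT5G59320	LTP3	guard_cell	induced	induced
AT5G59320	LTP3	leaf	induced	induced
AT4G21870	HSP	guard_cell	repressed	repressed
AT4G21870	HSP	leaf	repressed	repressed
AT1G34210	SERK2	guard_cell	repressed	repressed
AT1G34210	SERK2	leaf	repressed	repressed
AT5G52310	LTI78/RD29A	guard_cell	induced	induced
AT5G52310	LTI78/RD29A	leaf	none	induced
AT3G55940	PI-PLC	guard_cell	induced	induced
AT3G55940	PI-PLC	leaf	none	induced
AT4G35790	PLDdelta	guard_cell	induced	induced
AT4G35790	PLDdelta	leaf	none	none
AT4G01120	GBF2	guard_cell	induced	induced
AT4G01120	GBF2	leaf	none	none
AT1G77280	PK	guard_cell	induced	induced
AT1G77280	PK	leaf	none	none
AT5G40890	ATCLC-A	guard_cell	repressed	repressed
AT5G40890	ATCLC-A	leaf	none	none
AT5G46240	KAT1	guard_cell	repressed	repressed
AT5G46240	KAT1	leaf	none	none
AT1G02205	CER1	guard_cell	none	none
AT1G02205	CER1	leaf	induced	induced
AT5G49480	ATCP1	guard_cell	none	none
AT5G49480	ATCP1	leaf	induced	induced
AT1G21270	WAK2	guard_cell	none	none
AT1G21270	WAK2	leaf	repressed	repressed
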