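gene	probe_id	seq	start_nt	end_nt
phnA1a	phnA1a_MD_A	GTITGYAAYTAYCAYGGITGGGT	294	316
phnA1a	phnA1a_MD_B	CAYGARATHGARGTITGGACITA	957	979
phnA2a	phnA2a_MD_A	GARGAYATHCAYTAYTGGATGCC	123	145
phnA2a	phnA2a_MD_B	GGICARGTITGGATGGARGAYCC	261	284
ahdA1c	ahdA1c_MD_A	GARTGYGTITAYCAYCARTGGGC	318	340
ahdA1c	ahdA1c_MD_B	GAYGCIGCIGAYAARCARGCITA	771	793
ahdA2c	ahdA2c_MD_A	GAYGAYMGIYTIGARGARTGGCC	81	103
ahdA2c	ahdA2c_MD_B	ATHGAYACIATGATGGTIMGICC	459	481
bphB	bphB_MD_A	AAYGTIGGIATHTGGGAYTWYAT	261	283
bphB	bphB_MD_B	AAYBTIAARGGITAYTTYTTYGG	348	370
bphC	bphC_MD_A	CCITAYTTYATGCAYTGYAAYGA	558	580
bphC	bphC_MD_B	TGGYTITGGGARTTYGGITGGGG	777	799
bphA3	bphA3_MD_A	ATHATHGARTGYCCITTYCAYGG	180	202
bphA3	bphA3_MD_B	ATHGAIGAYGGITGGGTITGYAT	279	302
ahdA4	ahdA4_MD_A	GCIAAYGTICCIGAYAAYTTYTT	159	181
ahdA4	ahdA4_MD_B	CARGARACITAYCARAAYGCIGC	867	889
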