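haplotype	population	region	count	6	9	24	45	51	81	117	126	129	138	225	261	267	288	348	366	384	387	390	459	468	495	498	501	508	516	525	582
reference	.	.	0	T	A	A	T	A	A	A	G	T	C	T	A	G	C	C	A	A	T	T	T	A	A	A	T	T	C	A	G
Hap_1	NW	Northern	12	.	.	.	.	.	G	.	.	.	T	.	.	A	.	.	.	G	.	C	C	T	G	.	C	C	T	.	A
Hap_2	NW	Northern	3	.	.	G	.	.	G	.	.	.	T	.	.	A	.	.	.	G	.	C	C	T	G	.	C	C	T	.	A
Hap_3	NE	Northern	73	.	.	.	.	G	.	.	.	.	T	.	G	.	.	T	.	G	.	.	C	T	G	G	.	C	T	G	.
Hap_4	NE	Northern	22	.	.	.	.	G	.	.	.	.	.	.	G	.	.	T	.	G	.	.	C	T	G	G	.	C	T	G	.
Hap_5	NE	Northern	3	.	.	.	.	G	.	.	.	.	T	C	.	.	.	T	.	G	.	.	C	T	.	G	.	C	T	G	.
Hap_6	NE	Northern	4	.	.	.	.	G	.	.	.	.	T	.	.	.	.	T	.	G	.	.	C	T	G	G	.	C	T	G	.
Hap_7	SP	Southern	2	.	G	.	.	.	.	G	.	.	.	.	.	.	.	.	.	.	C	.	.	.	.	.	.	.	.	.	.
Hap_8	SP	Southern	109	.	G	.	.	.	.	G	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
Hap_9	SP	Southern	4	.	G	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
Hap_10	SP	Southern	1	.	G	.	.	.	.	G	.	.	.	.	.	.	.	.	G	.	.	.	.	.	.	.	.	.	.	.	.
Hap_11	SP	Southern	6	.	.	.	.	.	.	G	.	.	T	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
Hap_12	SP	Southern	1	.	G	.	.	.	.	G	.	C	.	.	.	.	T	.	.	.	.	.	.	.	.	.	.	.	.	.	.
Hap_13	SP	Southern	1	.	G	.	.	.	.	G	A	.	.	.	.	.	.	.	.	.	C	.	.	.	.	.	.	.	.	.	.
Hap_14	SP	Southern	1	.	G	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	G	.
Hap_15	SP	Southern	2	C	.	.	C	.	.	G	.	.	T	.	.	.	T	.	.	.	.	.	.	.	.	.	.	.	.	.	.
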