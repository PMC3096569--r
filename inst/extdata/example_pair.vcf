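##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	ind1	ind2	ind3	ind4	ind5	ind6	ind7	ind8	ind9	ind10	ind11	ind12	ind13	ind14	ind15	ind16	ind17	ind18	ind19	ind20	ind21	ind22	ind23	ind24	ind25	ind26	ind27	ind28	ind29	ind30	ind31	ind32	ind33	ind34	ind35	ind36	ind37	ind38	ind39	ind40	ind41	ind42	ind43	ind44	ind45	ind46	ind47	ind48	ind49	ind50	ind51	ind52	ind53	ind54	ind55	ind56	ind57	ind58	ind59	ind60
1	10100	rs_blockA_1	A	G	.	PASS	.	GT	1/1	0/1	1/1	0/1	1/1	0/1	1/1	1/1	1/1	0/1	0/0	0/1	0/1	1/1	0/0	1/1	1/1	0/1	0/1	0/1	1/1	0/1	0/0	0/1	1/1	1/1	0/0	0/0	0/1	1/1	1/1	1/1	0/0	1/1	1/1	1/1	0/1	0/1	1/1	0/0	0/1	1/1	1/1	0/1	0/0	0/1	1/1	1/1	0/0	1/1	0/1	0/0	0/1	0/1	0/1	1/1	0/0	0/1	1/1	1/1
1	10450	rs_blockA_2	C	T	.	PASS	.	GT	1/1	0/1	0/0	0/0	0/1	0/0	1/1	1/1	0/0	0/1	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/1	1/1	0/1	0/0	1/1	0/1	0/0	0/1	0/1	0/0	0/1	0/0	0/0	0/1	0/0	0/1	0/0	0/1	0/1	0/0	0/1	0/1	0/1	0/0	0/1	0/0	0/1	0/1	0/1	0/0	0/1	0/0	1/1	0/0	0/0	0/1	0/0
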