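sample	snpA	snpB
ind1	2	2
ind2	1	1
ind3	2	0
ind4	1	0
ind5	2	1
ind6	1	0
ind7	2	2
ind8	2	2
ind9	2	0
ind10	1	1
ind11	0	0
ind12	1	1
ind13	1	1
ind14	2	1
ind15	0	0
ind16	2	0
ind17	2	0
ind18	1	0
ind19	1	0
ind20	1	1
ind21	2	1
ind22	1	0
ind23	0	0
ind24	1	1
ind25	2	2
ind26	2	1
ind27	0	0
ind28	0	2
ind29	1	1
ind30	2	0
ind31	2	1
ind32	2	1
ind33	0	0
ind34	2	1
ind35	2	0
ind36	2	0
ind37	1	1
ind38	1	0
ind39	2	1
ind40	0	0
ind41	1	1
ind42	2	1
ind43	2	0
ind44	1	1
ind45	0	1
ind46	1	1
ind47	2	0
ind48	2	1
ind49	0	0
ind50	2	1
ind51	1	1
ind52	0	1
ind53	1	0
ind54	1	1
ind55	1	0
ind56	2	2
ind57	0	0
ind58	1	0
ind59	2	1
ind60	2	0
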