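Id	CoreId	MarkerName	Intensity	Range
SR1	CR1	Apaf-1	0	
SR2	CR2	Apaf-1	0	
SR3	CR3	Apaf-1	0	
SR4	CR4	Apaf-1	0	
SR5	CR5	Apaf-1	0	
SR6	CR6	Apaf-1	0	
SR7	CR7	Apaf-1	0	
SR8	CR8	Apaf-1	0	
SR9	CR9	Apaf-1	0	
SR10	CR10	Apaf-1	0	
SR11	CR11	Apaf-1	0	
SR12	CR12	Apaf-1	0	
SR13	CR13	Apaf-1	0	
SR14	CR14	Apaf-1	0	
SR15	CR15	Apaf-1	0	
SR16	CR16	Apaf-1	0	
SR17	CR17	Apaf-1	0	
SR18	CR18	Apaf-1	0	
SR19	CR19	Apaf-1	0	
SR20	CR20	Apaf-1	0	
SR21	CR21	Apaf-1	0	
SR22	CR22	Apaf-1	0	
SR23	CR23	Apaf-1	0	
SR24	CR24	Apaf-1	0	
SR25	CR25	Apaf-1	0	
SR26	CR26	Apaf-1	0	
SR27	CR27	Apaf-1	1	
SR28	CR28	Apaf-1	2	
SR29	CR29	Apaf-1	3	
SR30	CR30	Apaf-1	1	
SR31	CR31	Apaf-1	0	
SR32	CR32	Apaf-1	0	
SR33	CR33	Apaf-1	0	
SR34	CR34	Apaf-1	0	
SR35	CR35	Apaf-1	0	
SR36	CR36	Apaf-1	0	
SR37	CR37	Apaf-1	2	
SR38	CR38	Apaf-1	3	
SR39	CR39	Apaf-1	1	
SR40	CR40	Apaf-1	2	
SR41	CR41	Apaf-1	3	
SR42	CR42	Apaf-1	1	
SR43	CR43	Apaf-1	2	
SR44	CR44	Apaf-1	3	
SR45	CR45	Apaf-1	1	
SR46	CR46	Apaf-1	2	
SR47	CR47	Apaf-1	3	
SR48	CR48	Apaf-1	1	
SR49	CR49	Apaf-1	2	
SR50	CR50	Apaf-1	3	
SR51	CR51	Apaf-1	1	
SR52	CR52	Apaf-1	2	
SR53	CR53	Apaf-1	3	
SR54	CR54	Apaf-1	1	
SR55	CR55	Apaf-1	2	
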