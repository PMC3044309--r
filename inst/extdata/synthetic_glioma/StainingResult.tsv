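Id	CoreId	MarkerName	Intensity	Range
SR1	CR1	EGFR	3	
SR2	CR2	EGFR	2	
SR3	CR3	EGFR	2	
SR4	CR4	EGFR	1	
SR5	CR5	EGFR	3	
SR6	CR6	EGFR	2	
SR7	CR7	EGFR	2	
SR8	CR8	EGFR	1	
SR9	CR9	EGFR	3	
SR10	CR10	EGFR	2	
SR11	CR11	EGFR	2	
SR12	CR12	EGFR	1	
SR13	CR13	EGFR	3	
SR14	CR14	EGFR	2	
SR15	CR15	EGFR	2	
SR16	CR16	EGFR	1	
SR17	CR17	EGFR	0	
SR18	CR18	EGFR	1	
SR19	CR19	EGFR	2	
SR20	CR20	EGFR	0	
SR21	CR21	EGFR	1	
SR22	CR22	EGFR	2	
SR23	CR23	EGFR	0	
SR24	CR24	EGFR	1	
SR25	CR25	EGFR	2	
SR26	CR26	EGFR	0	
SR27	CR27	EGFR	1	
SR28	CR28	EGFR	2	
SR29	CR29	EGFR	0	
SR30	CR30	EGFR	1	
SR31	CR31	EGFR	0	
SR32	CR32	EGFR	1	
SR33	CR33	EGFR	0	
SR34	CR34	EGFR	1	
SR35	CR35	EGFR	0	
SR36	CR36	EGFR	1	
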