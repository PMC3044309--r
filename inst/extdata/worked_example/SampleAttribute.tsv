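Id	SampleId	AttributeName	Value
SA1	P1	Diagnosis	Colon cancer
SA2	P2	Diagnosis	Colon cancer
SA3	P3	Diagnosis	Colon cancer
SA4	P4	Diagnosis	Colon cancer
SA5	P5	Diagnosis	Colon cancer
SA6	P6	Diagnosis	Colon cancer
SA7	P7	Diagnosis	Colon cancer
SA8	P8	Diagnosis	Colon cancer
SA9	P9	Diagnosis	Colon cancer
SA10	P10	Diagnosis	Colon cancer
SA11	P11	Diagnosis	Colon cancer
SA12	P12	Diagnosis	Colon cancer
SA13	P13	Diagnosis	Colon cancer
SA14	P14	Diagnosis	Colon cancer
SA15	P15	Diagnosis	Colon cancer
SA16	P16	Diagnosis	Colon cancer
SA17	P17	Diagnosis	Colon cancer
SA18	P18	Diagnosis	Colon cancer
SA19	P19	Diagnosis	Colon cancer
SA20	P20	Diagnosis	Colon cancer
SA21	P21	Diagnosis	Colon cancer
SA22	P22	Diagnosis	Colon cancer
SA23	P23	Diagnosis	Colon cancer
SA24	P24	Diagnosis	Colon cancer
SA25	P25	Diagnosis	Colon cancer
SA26	P26	Diagnosis	Colon cancer
SA27	P27	Diagnosis	Colon cancer
SA28	P28	Diagnosis	Colon cancer
SA29	P29	Diagnosis	Colon cancer
SA30	P30	Diagnosis	Colon cancer
SA31	P31	Diagnosis	Colon cancer
SA32	P32	Diagnosis	Colon cancer
SA33	P33	Diagnosis	Colon cancer
SA34	P34	Diagnosis	Colon cancer
SA35	P35	Diagnosis	Colon cancer
SA36	P36	Diagnosis	Colon cancer
SA37	P37	Diagnosis	Colon cancer
SA38	P38	Diagnosis	Colon cancer
SA39	P39	Diagnosis	Colon cancer
SA40	P40	Diagnosis	Colon cancer
SA41	P41	Diagnosis	Colon cancer
SA42	P42	Diagnosis	Colon cancer
SA43	P43	Diagnosis	Colon cancer
SA44	P44	Diagnosis	Colon cancer
SA45	P45	Diagnosis	Colon cancer
SA46	P46	Diagnosis	Colon cancer
SA47	P47	Diagnosis	Colon cancer
SA48	P48	Diagnosis	Colon cancer
SA49	P49	Diagnosis	Colon cancer
SA50	P50	Diagnosis	Colon cancer
SA51	P51	Diagnosis	Colon cancer
SA52	P52	Diagnosis	Colon cancer
SA53	P53	Diagnosis	Colon cancer
SA54	P54	Diagnosis	Colon cancer
SA55	P55	Diagnosis	Colon cancer
SA56	P1	HistologicGrade	High-grade
SA57	P2	HistologicGrade	High-grade
SA58	P3	HistologicGrade	High-grade
SA59	P4	HistologicGrade	High-grade
SA60	P5	HistologicGrade	High-grade
SA61	P6	HistologicGrade	High-grade
SA62	P7	HistologicGrade	High-grade
SA63	P8	HistologicGrade	High-grade
SA64	P9	HistologicGrade	High-grade
SA65	P10	HistologicGrade	High-grade
SA66	P11	HistologicGrade	High-grade
SA67	P12	HistologicGrade	High-grade
SA68	P13	HistologicGrade	High-grade
SA69	P14	HistologicGrade	High-grade
SA70	P15	HistologicGrade	High-grade
SA71	P16	HistologicGrade	High-grade
SA72	P17	HistologicGrade	High-grade
SA73	P18	HistologicGrade	High-grade
SA74	P19	HistologicGrade	High-grade
SA75	P20	HistologicGrade	High-grade
SA76	P21	HistologicGrade	High-grade
SA77	P22	HistologicGrade	High-grade
SA78	P23	HistologicGrade	High-grade
SA79	P24	HistologicGrade	High-grade
SA80	P25	HistologicGrade	High-grade
SA81	P26	HistologicGrade	High-grade
SA82	P27	HistologicGrade	High-grade
SA83	P28	HistologicGrade	High-grade
SA84	P29	HistologicGrade	High-grade
SA85	P30	HistologicGrade	High-grade
SA86	P31	HistologicGrade	Low-grade
SA87	P32	HistologicGrade	Low-grade
SA88	P33	HistologicGrade	Low-grade
SA89	P34	HistologicGrade	Low-grade
SA90	P35	HistologicGrade	Low-grade
SA91	P36	HistologicGrade	Low-grade
SA92	P37	HistologicGrade	Low-grade
SA93	P38	HistologicGrade	Low-grade
SA94	P39	HistologicGrade	Low-grade
SA95	P40	HistologicGrade	Low-grade
SA96	P41	HistologicGrade	Low-grade
SA97	P42	HistologicGrade	Low-grade
SA98	P43	HistologicGrade	Low-grade
SA99	P44	HistologicGrade	Low-grade
SA100	P45	HistologicGrade	Low-grade
SA101	P46	HistologicGrade	Low-grade
SA102	P47	HistologicGrade	Low-grade
SA103	P48	HistologicGrade	Low-grade
SA104	P49	HistologicGrade	Low-grade
SA105	P50	HistologicGrade	Low-grade
SA106	P51	HistologicGrade	Low-grade
SA107	P52	HistologicGrade	Low-grade
SA108	P53	HistologicGrade	Low-grade
SA109	P54	HistologicGrade	Low-grade
SA110	P55	HistologicGrade	Low-grade
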