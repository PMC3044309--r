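Id	SlideId	SampleId
CR1	SL1	P1
CR2	SL2	P2
CR3	SL3	P3
CR4	SL4	P4
CR5	SL5	P5
CR6	SL1	P6
CR7	SL2	P7
CR8	SL3	P8
CR9	SL4	P9
CR10	SL5	P10
CR11	SL1	P11
CR12	SL2	P12
CR13	SL3	P13
CR14	SL4	P14
CR15	SL5	P15
CR16	SL1	P16
CR17	SL2	P17
CR18	SL3	P18
CR19	SL4	P19
CR20	SL5	P20
CR21	SL1	P21
CR22	SL2	P22
CR23	SL3	P23
CR24	SL4	P24
CR25	SL5	P25
CR26	SL1	P26
CR27	SL2	P27
CR28	SL3	P28
CR29	SL4	P29
CR30	SL5	P30
CR31	SL1	P31
CR32	SL2	P32
CR33	SL3	P33
CR34	SL4	P34
CR35	SL5	P35
CR36	SL1	P36
CR37	SL2	P37
CR38	SL3	P38
CR39	SL4	P39
CR40	SL5	P40
CR41	SL1	P41
CR42	SL2	P42
CR43	SL3	P43
CR44	SL4	P44
CR45	SL5	P45
CR46	SL1	P46
CR47	SL2	P47
CR48	SL3	P48
CR49	SL4	P49
CR50	SL5	P50
CR51	SL1	P51
CR52	SL2	P52
CR53	SL3	P53
CR54	SL4	P54
CR55	SL5	P55
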