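Id	SlideId	SampleId
CR1	SL1	G1
CR2	SL2	G2
CR3	SL1	G3
CR4	SL2	G4
CR5	SL1	G5
CR6	SL2	G6
CR7	SL1	G7
CR8	SL2	G8
CR9	SL1	G9
CR10	SL2	G10
CR11	SL1	G11
CR12	SL2	G12
CR13	SL1	G13
CR14	SL2	G14
CR15	SL1	G15
CR16	SL2	G16
CR17	SL1	G17
CR18	SL2	G18
CR19	SL1	G19
CR20	SL2	G20
CR21	SL1	G21
CR22	SL2	G22
CR23	SL1	G23
CR24	SL2	G24
CR25	SL1	G25
CR26	SL2	G26
CR27	SL1	G27
CR28	SL2	G28
CR29	SL1	G29
CR30	SL2	G30
CR31	SL1	G31
CR32	SL2	G32
CR33	SL1	G33
CR34	SL2	G34
CR35	SL1	G35
CR36	SL2	G36
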