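Id	ExperimentId	BlockId	MarkerName
SL1	E1	B1	Apaf-1
SL2	E1	B2	Apaf-1
SL3	E2	B3	Apaf-1
SL4	E2	B4	Apaf-1
SL5	E3	B5	Apaf-1
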