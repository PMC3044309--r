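Id	ExperimentId	BlockId	MarkerName
SL1	E1	B1	EGFR
SL2	E1	B2	EGFR
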