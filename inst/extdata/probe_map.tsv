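probe_id	antibody
201983_s_at	EGFR
204686_at	Apaf-1
211300_s_at	Leptin
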