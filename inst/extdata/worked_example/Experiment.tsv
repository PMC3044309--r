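Id	Name	ExpType
E1	colonTMA1	TMA
E2	colonTMA2	TMA
E3	colonTMA3	TMA
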