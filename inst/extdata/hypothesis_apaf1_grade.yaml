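shared_value: Colon cancer
classifier_attribute: Apaf-1 Intensity
classifier_values:
- '0'
dependent_attribute: HistologicGrade
dependent_values:
- High-grade
direction: negative
alpha: 0.01
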