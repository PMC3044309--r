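- attribute: Diagnosis
  context: '*'
  values:
  - Colon cancer
  - Stomach cancer
  - Glioma
  ordinal: no
- attribute: HistologicGrade
  context: Colon cancer
  values:
  - Low-grade
  - Intermediate-grade
  - High-grade
  ordinal: yes
- attribute: Apaf-1 Intensity
  context: Colon cancer
  values:
  - '0'
  - '1'
  - '2'
  - '3'
  ordinal: yes
- attribute: Intensity
  context: '*'
  values:
  - '0'
  - '1'
  - '2'
  - '3'
  ordinal: yes
- attribute: NodalStatus
  context: '*'
  values:
  - N0
  - N1
  - N2
  - N3
  ordinal: yes
- attribute: Histology
  context: '*'
  values:
  - Glioblastoma
  - Astrocytoma
  - Oligodendroglioma
  - Ependymoma
  ordinal: no
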