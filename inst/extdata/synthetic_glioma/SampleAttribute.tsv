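Id	SampleId	AttributeName	Value
SA1	G1	Diagnosis	Glioma
SA2	G2	Diagnosis	Glioma
SA3	G3	Diagnosis	Glioma
SA4	G4	Diagnosis	Glioma
SA5	G5	Diagnosis	Glioma
SA6	G6	Diagnosis	Glioma
SA7	G7	Diagnosis	Glioma
SA8	G8	Diagnosis	Glioma
SA9	G9	Diagnosis	Glioma
SA10	G10	Diagnosis	Glioma
SA11	G11	Diagnosis	Glioma
SA12	G12	Diagnosis	Glioma
SA13	G13	Diagnosis	Glioma
SA14	G14	Diagnosis	Glioma
SA15	G15	Diagnosis	Glioma
SA16	G16	Diagnosis	Glioma
SA17	G17	Diagnosis	Glioma
SA18	G18	Diagnosis	Glioma
SA19	G19	Diagnosis	Glioma
SA20	G20	Diagnosis	Glioma
SA21	G21	Diagnosis	Glioma
SA22	G22	Diagnosis	Glioma
SA23	G23	Diagnosis	Glioma
SA24	G24	Diagnosis	Glioma
SA25	G25	Diagnosis	Glioma
SA26	G26	Diagnosis	Glioma
SA27	G27	Diagnosis	Glioma
SA28	G28	Diagnosis	Glioma
SA29	G29	Diagnosis	Glioma
SA30	G30	Diagnosis	Glioma
SA31	G31	Diagnosis	Glioma
SA32	G32	Diagnosis	Glioma
SA33	G33	Diagnosis	Glioma
SA34	G34	Diagnosis	Glioma
SA35	G35	Diagnosis	Glioma
SA36	G36	Diagnosis	Glioma
SA37	G1	Histology	Glioblastoma
SA38	G2	Histology	Glioblastoma
SA39	G3	Histology	Glioblastoma
SA40	G4	Histology	Glioblastoma
SA41	G5	Histology	Glioblastoma
SA42	G6	Histology	Glioblastoma
SA43	G7	Histology	Glioblastoma
SA44	G8	Histology	Glioblastoma
SA45	G9	Histology	Glioblastoma
SA46	G10	Histology	Glioblastoma
SA47	G11	Histology	Glioblastoma
SA48	G12	Histology	Glioblastoma
SA49	G13	Histology	Glioblastoma
SA50	G14	Histology	Glioblastoma
SA51	G15	Histology	Glioblastoma
SA52	G16	Histology	Glioblastoma
SA53	G17	Histology	Astrocytoma
SA54	G18	Histology	Astrocytoma
SA55	G19	Histology	Astrocytoma
SA56	G20	Histology	Astrocytoma
SA57	G21	Histology	Astrocytoma
SA58	G22	Histology	Astrocytoma
SA59	G23	Histology	Astrocytoma
SA60	G24	Histology	Astrocytoma
SA61	G25	Histology	Astrocytoma
SA62	G26	Histology	Astrocytoma
SA63	G27	Histology	Astrocytoma
SA64	G28	Histology	Astrocytoma
SA65	G29	Histology	Oligodendroglioma
SA66	G30	Histology	Oligodendroglioma
SA67	G31	Histology	Oligodendroglioma
SA68	G32	Histology	Oligodendroglioma
SA69	G33	Histology	Oligodendroglioma
SA70	G34	Histology	Oligodendroglioma
SA71	G35	Histology	Oligodendroglioma
SA72	G36	Histology	Oligodendroglioma
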