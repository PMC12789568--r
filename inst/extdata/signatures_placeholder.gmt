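M1_polarization	placeholder_M1_set_edit_before_use	CD68	IL1B	CXCL9	CXCL10	TNF	NOS2	CD86
M2_polarization	placeholder_M2_set_edit_before_use	CD163	MRC1	CCL22	IL10	TGFB1	MSR1	CD206
Angiogenesis	placeholder_angiogenesis_set_edit_before_use	VEGFA	PECAM1	KDR	ANGPT2	TEK	CD34
Phagocytosis	placeholder_phagocytosis_set_edit_before_use	C1QC	C1QA	C1QB	MERTK	CD14	FCGR1A
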