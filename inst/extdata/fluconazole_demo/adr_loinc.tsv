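pt_name	loinc_id	common_name	direction	site_id	local_code	local_name
Hypokalemia	2823_3	Potassium (moles/volume) in serum or plasma	low	SNUH	L3044	Potassium (serum)
Hypokalemia	2823_3	Potassium (moles/volume) in serum or plasma	low	AJUH	35	Potassium
Hepatic function abnormal	1742_6	Alanine aminotransferase (enzymatic activity/volume) in serum or plasma	high	SNUH	L3012	ALT (serum)
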