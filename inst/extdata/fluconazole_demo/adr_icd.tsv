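pt_name	icd10_code	icd10_name
Hypokalemia	E87.6	Hypokalemia
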