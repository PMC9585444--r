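drug_id	name	atc_codes
D_FLZ	fluconazole	J02AC01
D_FAM	famotidine	A02BA03
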